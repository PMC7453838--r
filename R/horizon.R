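#' Spherical-earth horizon model
#'
#' The astronomical horizon of a perfectly spherical earth: sight lines
#' tangent to the sphere, dipped below the horizontal by
#' `arccos(R / (R + h))` for a camera at height `h`. For small heights this
#' is well approximated by `sqrt(2 h / R)` radians.
#'
#' @param earth_radius_m earth radius in metres (default 6 371 000).
#' @return An object of class `"horizon_model"`.
#' @export
horizon_model <- function(earth_radius_m = 6371000) {
  stopifnot(is.numeric(earth_radius_m), earth_radius_m > 0)
  structure(list(earth_radius_m = as.numeric(earth_radius_m)),
            class = "horizon_model")
}

#' Horizon dip angle
#'
#' @param elevation_m camera height above the reference sphere, m (>= 0).
#' @param hm a [horizon_model()].
#' @return Dip of the horizon below the horizontal, degrees.
#' @export
horizon_dip <- function(elevation_m, hm = horizon_model()) {
  stopifnot(all(elevation_m >= 0))
  R <- hm$earth_radius_m
  .rad2deg(acos(R / (R + elevation_m)))
}

## World-frame unit directions toward the horizon at the given azimuths
## (degrees, clockwise from +y).
.horizon_dirs <- function(azimuth_deg, dip_deg) {
  az <- .deg2rad(azimuth_deg)
  dp <- .deg2rad(dip_deg)
  cbind(cos(dp) * sin(az), cos(dp) * cos(az), -sin(dp) + 0 * az)
}

#' Trace of the horizon line in the image
#'
#' Projects the astronomical horizon (the cone of sight lines dipped
#' `arccos(R/(R+h))` below horizontal, across all azimuths) into the image
#' and returns points of the trace that fall inside the image rectangle.
#' For a rectilinear camera with roll 0 the trace is a horizontal line.
#'
#' @param intr,pose the camera; `pose$elevation_m` sets the dip.
#' @param hm a [horizon_model()].
#' @param n_points number of trace points requested.
#' @return An n x 2 matrix of pixel coordinates (0 rows when the horizon is
#'   entirely outside the frame).
#' @export
horizon_in_image <- function(intr, pose, hm = horizon_model(),
                             n_points = 100) {
  stopifnot(pose$elevation_m > 0, n_points >= 1)
  dip <- horizon_dip(pose$elevation_m, hm)
  az <- pose$heading_deg + seq(-180, 180, by = 0.1)
  dirs <- .horizon_dirs(az, dip)
  dc <- dirs %*% t(pose_rotation(pose))
  res <- .camera_to_pixel(dc, intr)
  uv <- res$uv[res$visible, , drop = FALSE]
  if (nrow(uv) == 0) return(uv)
  idx <- unique(round(seq(1, nrow(uv), length.out = min(n_points, nrow(uv)))))
  uv[idx, , drop = FALSE]
}

## Pixel distances from clicked points to the model horizon trace. The
## projected horizon is a conic, not exactly a straight line, so each click
## is compared with the horizon point at the click's own viewing azimuth
## (the trace point in the click's vertical plane). This is exact for
## clicks on the trace, first-order perpendicular near it (the trace is
## locally horizontal), and valid for all projection models. Returns NULL
## when the horizon does not project in front of the camera.
.horizon_distances <- function(uv, intr, pose, hm = horizon_model()) {
  uv <- .as_points2(uv)
  dip <- horizon_dip(pose$elevation_m, hm)
  ray <- pixel_ray(uv, intr, pose)
  az <- .rad2deg(atan2(ray$dir[, 1], ray$dir[, 2]))
  dc <- .horizon_dirs(az, dip) %*% t(pose_rotation(pose))
  if (intr$projection == "rectilinear" && any(dc[, 3] <= 0)) return(NULL)
  p <- .camera_to_pixel(dc, intr)$uv
  if (any(!is.finite(p))) return(NULL)
  sqrt(rowSums((uv - p)^2))
}
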