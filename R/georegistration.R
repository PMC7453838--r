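#' Convert latitude/longitude to local tangent-plane metres
#'
#' Equirectangular approximation about a reference point: metres east (x)
#' and north (y) of `(ref_lat, ref_lon)`. Adequate for scenes up to a few
#' kilometres; [local_to_latlon()] is the exact inverse of this
#' approximation (round-trip below 1e-9 degrees).
#'
#' @param lat,lon coordinates to convert, degrees.
#' @param ref_lat,ref_lon reference origin, degrees.
#' @param earth_radius_m earth radius, m.
#' @return `latlon_to_local`: matrix with columns `x_m`, `y_m`.
#' @export
latlon_to_local <- function(lat, lon, ref_lat, ref_lon,
                            earth_radius_m = 6371000) {
  stopifnot(all(abs(lat) <= 90), abs(ref_lat) <= 90)
  k <- pi / 180 * earth_radius_m
  cbind(x_m = (lon - ref_lon) * k * cos(.deg2rad(ref_lat)),
        y_m = (lat - ref_lat) * k)
}

#' @param x_m,y_m local coordinates to convert back, metres.
#' @return `local_to_latlon`: matrix with columns `lat`, `lon`.
#' @rdname latlon_to_local
#' @export
local_to_latlon <- function(x_m, y_m, ref_lat, ref_lon,
                            earth_radius_m = 6371000) {
  k <- pi / 180 * earth_radius_m
  cbind(lat = ref_lat + y_m / k,
        lon = ref_lon + x_m / (k * cos(.deg2rad(ref_lat))))
}

#' Landmark correspondences between image and map
#'
#' @param image_points n x 2 matrix of pixel coordinates.
#' @param target_points n x 2 matrix of map coordinates in metres (local
#'   tangent frame; convert geographic coordinates with
#'   [latlon_to_local()]). Pairing is by row.
#' @return An object of class `"landmark_set"`. At least 3 pairs are
#'   required (the fit has up to 6 parameters); nearly collinear targets
#'   trigger a warning because they leave the pose ill-constrained.
#' @export
landmark_set <- function(image_points, target_points) {
  image_points <- .as_points2(image_points)
  target_points <- .as_points2(target_points)
  if (nrow(image_points) != nrow(target_points))
    stop("image and target points must be paired (equal length)")
  if (nrow(image_points) < 3)
    stop("at least 3 landmark pairs are required")
  ctr <- sweep(target_points, 2, colMeans(target_points))
  sv <- svd(ctr)$d
  if (sv[2] < 1e-6 * max(sv[1], 1))
    warning("target landmarks are (nearly) collinear; the fit will be ",
            "ill-constrained")
  structure(list(image_points = image_points, target_points = target_points),
            class = "landmark_set")
}

.params_to_pose_geo <- function(params, roll_deg = 0) {
  p <- as.list(params)
  structure(list(elevation_m = p$elevation, tilt_deg = p$tilt,
                 roll_deg = p$roll %||% roll_deg,
                 heading_deg = (p$heading %||% 0) %% 360,
                 pos_x_m = p$pos_x %||% 0, pos_y_m = p$pos_y %||% 0),
            class = "camera_pose")
}

#' Ground-distance cost of a candidate camera for landmark registration
#'
#' Backprojects the image landmarks onto the ground plane under the
#' candidate pose and returns the RMS Euclidean distance (metres) to the
#' map targets. Candidate poses for which some landmark has no ground
#' intersection (above the horizon) get a large finite penalty so
#' optimisers and samplers remain total.
#'
#' @param params named numeric vector with `elevation` (m), `tilt`,
#'   `heading` (deg), `pos_x`, `pos_y` (m), optionally `roll`.
#' @param lm a [landmark_set()].
#' @param intr a [camera_intrinsics()].
#' @return RMS ground distance in metres (or a penalty >= 1e6).
#' @export
registration_cost <- function(params, lm, intr) {
  pose <- .params_to_pose_geo(params)
  if (is.null(pose$elevation_m) || pose$elevation_m <= 0 ||
      pose$tilt_deg < 0 || pose$tilt_deg >= 180) return(1e6)
  g <- backproject_to_plane(lm$image_points, intr, pose, z_plane = 0,
                            allow_miss = TRUE)
  if (any(!is.finite(g[, 1]))) return(1e6 + sum(!is.finite(g[, 1])))
  sqrt(mean((g[, 1] - lm$target_points[, 1])^2 +
              (g[, 2] - lm$target_points[, 2])^2))
}

#' Fit camera pose by geo-referencing landmarks
#'
#' Estimates elevation, tilt, x/y position and heading (roll optionally) of
#' a camera by registering backprojected image landmarks to known map
#' coordinates: Metropolis sampling under a Gaussian measurement model on
#' the ground-plane distances, preceded by a multi-start mode search, and
#' followed by a deterministic Nelder-Mead refinement of the posterior
#' mean. Useful for near-nadir imagery (aircraft) where object sizes vary
#' too little for the object-height fit.
#'
#' @param lm a [landmark_set()].
#' @param intr a [camera_intrinsics()].
#' @param noise_m measurement noise of the ground distances, metres.
#' @param fit_roll also sample roll (default `FALSE`: near-nadir images
#'   make roll and heading partially degenerate, and the fit then has 5
#'   parameters).
#' @param n_iter total Metropolis iterations (20% burn-in discarded).
#' @param seed integer seed.
#' @param init optional named start vector; otherwise multi-start search.
#' @param refine run the deterministic refinement (default `TRUE`).
#' @param elevation_range,tilt_range flat-prior supports.
#' @return A `"chain_summary"` over `elevation_m`, `tilt_deg`, `pos_x_m`,
#'   `pos_y_m`, `heading_deg` (and `roll_deg` if fitted), with extra
#'   elements `refined` (named vector, the refined point estimate) and
#'   `refined_cost` (its RMS ground distance, m).
#' @export
fit_georeference <- function(lm, intr, noise_m = 1, fit_roll = FALSE,
                             n_iter = 10000, seed = NULL, init = NULL,
                             refine = TRUE,
                             elevation_range = c(1, 5000),
                             tilt_range = c(0, 120)) {
  stopifnot(inherits(lm, "landmark_set"))
  if (!is.null(seed)) set.seed(seed)
  par_names <- c("elevation", "tilt", "pos_x", "pos_y", "heading",
                 if (fit_roll) "roll")
  tgt <- lm$target_points
  span <- max(apply(tgt, 2, function(z) diff(range(z))), 10)
  lo <- c(elevation_range[1], tilt_range[1],
          min(tgt[, 1]) - 3 * span, min(tgt[, 2]) - 3 * span, -360,
          if (fit_roll) -45)
  hi <- c(elevation_range[2], tilt_range[2],
          max(tgt[, 1]) + 3 * span, max(tgt[, 2]) + 3 * span, 720,
          if (fit_roll) 45)
  n_lm <- nrow(lm$image_points)
  loglik <- function(p) {
    if (any(p < lo) || any(p > hi)) return(-Inf)
    pose <- .params_to_pose_geo(p)
    g <- backproject_to_plane(lm$image_points, intr, pose, z_plane = 0,
                              allow_miss = TRUE)
    miss <- !is.finite(g[, 1])
    d2 <- (g[, 1] - tgt[, 1])^2 + (g[, 2] - tgt[, 2])^2
    d2[miss] <- (1e4)^2
    -sum(d2) / (2 * noise_m^2) - 2 * n_lm * log(noise_m)
  }
  draw_init <- function() {
    s <- c(exp(stats::runif(1, log(pmax(elevation_range[1], 5)),
                            log(elevation_range[2]))),
           stats::runif(1, 5, 60),
           stats::runif(1, min(tgt[, 1]) - span, max(tgt[, 1]) + span),
           stats::runif(1, min(tgt[, 2]) - span, max(tgt[, 2]) + span),
           stats::runif(1, 0, 360),
           if (fit_roll) stats::runif(1, -5, 5))
    stats::setNames(s, par_names)
  }
  if (is.null(init)) init <- draw_init()
  else init <- stats::setNames(as.numeric(init), par_names)
  init <- .mode_search(loglik, init, draw_init, n_starts = 25,
                       lo = lo, hi = hi)
  scales <- c(noise_m, 0.2, noise_m, noise_m, 0.5, if (fit_roll) 0.2)
  ch <- metropolis_sample(loglik, init, scales, n_iter = n_iter, seed = NULL)
  samples <- ch$samples
  samples[, "heading"] <- samples[, "heading"] %% 360
  colnames(samples) <- c("elevation_m", "tilt_deg", "pos_x_m", "pos_y_m",
                         "heading_deg", if (fit_roll) "roll_deg")
  out <- chain_summary(samples, acceptance_rate = ch$acceptance_rate,
                       seed = seed, proposal_scales = ch$proposal_scales)
  if (refine) {
    start <- stats::setNames(colMeans(ch$samples), par_names)
    ref <- stats::optim(start, function(p) registration_cost(p, lm, intr),
                        method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-14))
    ## polish: restart once from the optimum (Nelder-Mead stalls otherwise)
    ref <- stats::optim(ref$par, function(p) registration_cost(p, lm, intr),
                        method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-14))
    refined <- ref$par
    refined["heading"] <- refined["heading"] %% 360
    out$refined <- refined
    out$refined_cost <- ref$value
  }
  out
}
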