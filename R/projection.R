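## Geometry core: rigid world->camera transform, forward projection for the
## three supported lens models, radial distortion, and constrained
## backprojection. All functions are vectorised over points: a point argument
## is a length-3 (or length-2) vector or an n x 3 (n x 2) matrix.

.as_points3 <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3, byrow = TRUE)
  storage.mode(p) <- "double"
  if (ncol(p) != 3) stop("world points must have 3 columns (x, y, z)")
  p
}

.as_points2 <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2, byrow = TRUE)
  storage.mode(p) <- "double"
  if (ncol(p) != 2) stop("image points must have 2 columns (u, v)")
  p
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Rotation matrix of a camera pose
#'
#' Returns the 3 x 3 matrix `R` mapping world-frame direction vectors to
#' camera-frame vectors (x right, y down, z along the optical axis), composed
#' as `R_roll %*% R_tilt %*% R_heading`. Heading rotates about the world z
#' axis (clockwise from +y), tilt about the camera x axis (0 = nadir), roll
#' about the optical axis.
#'
#' @param pose a [camera_pose()] object.
#' @return A 3 x 3 rotation matrix.
#' @export
pose_rotation <- function(pose) {
  th <- .deg2rad(pose$tilt_deg)
  rl <- .deg2rad(pose$roll_deg)
  hd <- .deg2rad(pose$heading_deg)
  Rh <- rbind(c(cos(hd), -sin(hd), 0),
              c(sin(hd),  cos(hd), 0),
              c(0, 0, 1))
  Rt <- rbind(c(1, 0, 0),
              c(0, -cos(th), -sin(th)),
              c(0,  sin(th), -cos(th)))
  Rr <- rbind(c(cos(rl),  sin(rl), 0),
              c(-sin(rl), cos(rl), 0),
              c(0, 0, 1))
  Rr %*% Rt %*% Rh
}

.camera_center <- function(pose) c(pose$pos_x_m, pose$pos_y_m, pose$elevation_m)

#' Transform world points to camera-frame coordinates
#'
#' Applies the rigid transform of a pose: translation by minus the camera
#' centre, then the pose rotation. Camera frame: x right, y down (image
#' convention), z forward along the optical axis, all in metres.
#'
#' @param p world point(s): length-3 vector or n x 3 matrix `(x, y, z)` m.
#' @param pose a [camera_pose()] object.
#' @return n x 3 matrix of camera-frame coordinates.
#' @export
world_to_camera <- function(p, pose) {
  p <- .as_points3(p)
  ctr <- .camera_center(pose)
  dp <- sweep(p, 2, ctr)
  dp %*% t(pose_rotation(pose))
}

#' Apply or invert radial lens distortion
#'
#' The distortion acts on normalized image coordinates (pixel offsets from
#' the principal point divided by the effective focal length):
#' `r' = r * (1 + k1 r^2 + k2 r^4 + k3 r^6)`. The inverse has no closed form
#' and is computed by Newton iteration on the radius.
#'
#' @param ab normalized coordinates: length-2 vector or n x 2 matrix.
#' @param k distortion triple `(k1, k2, k3)`.
#' @return Distorted (resp. undistorted) coordinates, same shape as input.
#' @export
apply_distortion <- function(ab, k) {
  ab <- .as_points2(ab)
  if (all(k == 0)) return(ab)
  r2 <- ab[, 1]^2 + ab[, 2]^2
  fac <- 1 + k[1] * r2 + k[2] * r2^2 + k[3] * r2^3
  ab * fac
}

#' @param tol convergence tolerance on the radius, normalized units.
#' @param max_iter maximum Newton iterations before failing.
#' @rdname apply_distortion
#' @export
invert_distortion <- function(ab, k, tol = 1e-10, max_iter = 50) {
  ab <- .as_points2(ab)
  if (all(k == 0)) return(ab)
  rd <- sqrt(ab[, 1]^2 + ab[, 2]^2)   # distorted radius
  r <- rd                              # undistorted radius, initial guess
  done <- rd == 0
  for (i in seq_len(max_iter)) {
    if (all(done)) break
    r2 <- r^2
    g  <- r * (1 + k[1] * r2 + k[2] * r2^2 + k[3] * r2^3) - rd
    gp <- 1 + 3 * k[1] * r2 + 5 * k[2] * r2^2 + 7 * k[3] * r2^3
    step <- g / gp
    step[done | !is.finite(step)] <- 0
    r <- r - step
    done <- done | abs(step) < tol
  }
  if (!all(done))
    stop("distortion inversion did not converge; coefficients too extreme ",
         "for the requested radius")
  scale <- ifelse(rd > 0, r / rd, 1)
  ab * scale
}

## Forward map camera-frame coordinates -> pixel coordinates.
## Returns list(uv, visible, behind). Used by project() and for direction
## vectors (horizon, epipolar geometry), which are just points at infinity.
.camera_to_pixel <- function(pc, intr) {
  x <- pc[, 1]; y <- pc[, 2]; z <- pc[, 3]
  f <- effective_focal_length(intr)
  w <- intr$image_width_px; h <- intr$image_height_px
  behind <- rep(FALSE, nrow(pc))
  if (intr$projection == "rectilinear") {
    behind <- z <= 0
    a <- ifelse(behind, NA_real_, x / z)
    b <- ifelse(behind, NA_real_, y / z)
  } else {
    rho <- sqrt(x^2 + z^2)
    a <- atan2(x, z)
    b <- if (intr$projection == "cylindrical") y / rho else atan2(y, rho)
    degen <- rho == 0 & y == 0
    a[degen] <- NA_real_; b[degen] <- NA_real_
    behind <- degen
  }
  ab <- apply_distortion(cbind(a, b), intr$distortion)
  u <- f * ab[, 1] + w / 2
  v <- f * ab[, 2] + h / 2
  visible <- !behind & is.finite(u) & is.finite(v) &
    u >= 0 & u <= w & v >= 0 & v <= h
  list(uv = cbind(u_px = u, v_px = v), visible = visible, behind = behind)
}

#' Project world points into the image
#'
#' Maps metric world points to (sub-pixel, top-left-origin) image
#' coordinates under the camera's projection model, with radial distortion
#' applied in normalized coordinates. For the rectilinear (pinhole) model,
#' points at or behind the image plane (`z_c <= 0`) cannot be projected:
#' their coordinates are set to the sentinel `NA` and flagged not visible,
#' so batch projection of mixed point sets never throws.
#'
#' @param p world point(s), length-3 vector or n x 3 matrix, metres.
#' @param intr a [camera_intrinsics()] object.
#' @param pose a [camera_pose()] object.
#' @return A list with `uv` (n x 2 matrix of pixel coordinates) and
#'   `visible` (logical: in front of the camera and inside the image
#'   rectangle).
#' @export
project <- function(p, intr, pose) {
  pc <- world_to_camera(p, pose)
  res <- .camera_to_pixel(pc, intr)
  list(uv = res$uv, visible = res$visible)
}

## Pixel -> unit-free ray direction in the CAMERA frame (not normalised).
.pixel_to_camera_dir <- function(uv, intr) {
  uv <- .as_points2(uv)
  f <- effective_focal_length(intr)
  a <- (uv[, 1] - intr$image_width_px / 2) / f
  b <- (uv[, 2] - intr$image_height_px / 2) / f
  ab <- invert_distortion(cbind(a, b), intr$distortion)
  a <- ab[, 1]; b <- ab[, 2]
  switch(intr$projection,
         rectilinear = cbind(a, b, 1),
         cylindrical = cbind(sin(a), b, cos(a)),
         equirectangular = cbind(cos(b) * sin(a), sin(b), cos(b) * cos(a)))
}

#' Cast pixel rays into the world
#'
#' Returns, for each pixel, the camera centre and the world-frame direction
#' of the viewing ray through that pixel (undistorted, per the camera's
#' projection model). Directions are not normalised.
#'
#' @inheritParams backproject_to_plane
#' @return A list with `origin` (length-3 camera centre) and `dir`
#'   (n x 3 matrix of ray directions).
#' @export
pixel_ray <- function(uv, intr, pose) {
  dc <- .pixel_to_camera_dir(uv, intr)
  list(origin = .camera_center(pose), dir = dc %*% pose_rotation(pose))
}

#' Backproject image points onto a horizontal plane
#'
#' Inverts the projection under the constraint that the world point lies on
#' the plane `z = z_plane`: the viewing ray of each pixel is intersected
#' with that plane. Only intersections in front of the camera are accepted;
#' pixels whose ray is parallel to the plane or points away from it (for
#' example pixels above the horizon when the plane is below the camera) have
#' no ground intersection.
#'
#' @param uv image point(s): length-2 vector or n x 2 matrix `(u, v)` px.
#' @param intr a [camera_intrinsics()] object.
#' @param pose a [camera_pose()] object.
#' @param z_plane height of the target plane, m (default 0, the ground).
#' @param allow_miss if `TRUE`, pixels without a forward intersection yield
#'   `NA` rows instead of an error (useful for batch evaluation inside
#'   samplers).
#' @return n x 3 matrix of world coordinates on the plane.
#' @export
backproject_to_plane <- function(uv, intr, pose, z_plane = 0,
                                 allow_miss = FALSE) {
  ray <- pixel_ray(uv, intr, pose)
  dz <- ray$dir[, 3]
  tt <- (z_plane - ray$origin[3]) / dz
  ## rays within ~1e-12 of parallel would "intersect" astronomically far
  ## away; treat them as parallel
  near_par <- abs(dz) < 1e-12 * sqrt(rowSums(ray$dir^2))
  bad <- !is.finite(tt) | tt <= 0 | near_par
  if (any(bad) && !allow_miss)
    stop("no ground intersection: ray parallel to or pointing away from ",
         "the plane for ", sum(bad), " pixel(s)")
  tt[bad] <- NA_real_
  out <- cbind(x_m = ray$origin[1] + tt * ray$dir[, 1],
               y_m = ray$origin[2] + tt * ray$dir[, 2],
               z_m = z_plane + 0 * tt)
  out
}

#' Backproject a head pixel constrained to the foot's horizontal position
#'
#' Given the world position of an object's base (foot) on the ground and the
#' pixel of its top (head), recovers the head's world point under the
#' constraint that it lies on the vertical axis through the foot. The
#' returned point is the point on the head-pixel ray closest to that
#' vertical axis; its z coordinate is the estimated object height.
#'
#' @param head_uv head pixel(s), length-2 vector or n x 2 matrix.
#' @param foot_world corresponding foot world point(s) (n x 3), typically
#'   from [backproject_to_plane()].
#' @param intr,pose the camera.
#' @param allow_miss if `TRUE`, degenerate pairs (ray parallel to the
#'   vertical, or closest approach behind the camera) yield `NA` rows
#'   instead of an error.
#' @return n x 3 matrix of head world coordinates; column `z_m` is the
#'   estimated height above the foot plane.
#' @export
backproject_with_foot_constraint <- function(head_uv, foot_world, intr, pose,
                                             allow_miss = FALSE) {
  foot_world <- .as_points3(foot_world)
  ray <- pixel_ray(head_uv, intr, pose)
  d <- ray$dir
  if (nrow(d) != nrow(foot_world))
    stop("head_uv and foot_world must have the same number of points")
  ## closest point on ray origin + s*d to the vertical line through the foot
  w0x <- ray$origin[1] - foot_world[, 1]
  w0y <- ray$origin[2] - foot_world[, 2]
  w0z <- ray$origin[3]                       # foot axis passes through z = 0
  aa <- rowSums(d^2)
  bb <- d[, 3]
  d1 <- d[, 1] * w0x + d[, 2] * w0y + d[, 3] * w0z
  denom <- aa - bb^2                          # = |d_horizontal|^2
  s <- (bb * w0z - d1) / denom
  bad <- !is.finite(s) | s <= 0 | denom < .Machine$double.eps * aa
  if (any(bad) && !allow_miss)
    stop("head ray diverging from the vertical axis through the foot for ",
         sum(bad), " pair(s)")
  s[bad] <- NA_real_
  cbind(x_m = ray$origin[1] + s * d[, 1],
        y_m = ray$origin[2] + s * d[, 2],
        z_m = ray$origin[3] + s * d[, 3])
}
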