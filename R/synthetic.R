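#' Default survey camera
#'
#' The wide-angle survey configuration used throughout the synthetic
#' experiments: focal length 14 mm, sensor 17.3 x 9.7 mm, image
#' 4608 x 2592 px, rectilinear, no distortion.
#'
#' @return A [camera_intrinsics()] object.
#' @export
default_intrinsics <- function() {
  camera_intrinsics(14, 17.3, 9.7, 4608, 2592)
}

#' Default survey pose
#'
#' Elevation 16.1 m, tilt 85.3 deg, roll 0.3 deg: a camera overlooking a
#' flat plane from a small rise, almost horizontal.
#'
#' @return A [camera_pose()] object.
#' @export
default_pose <- function() camera_pose(16.1, 85.3, 0.3)

#' Specification of a synthetic object scene
#'
#' Describes the ground-truth world emulated by [generate_object_scene()]:
#' upright objects of fixed size scattered on a flat ground plane in front
#' of a known camera, annotated with noisy foot/head clicks.
#'
#' @param n_objects number of objects (>= 1).
#' @param object_height_m,object_width_m object dimensions, m.
#' @param distance_range_m range `c(min, max)` of ground distances from the
#'   camera, m.
#' @param intrinsics,pose the generating (truth) camera.
#' @param click_noise_px isotropic Gaussian click noise, pixels.
#' @param seed integer seed for reproducible scenes.
#' @return An object of class `"scene_spec"`.
#' @export
scene_spec <- function(n_objects = 50, object_height_m = 0.75,
                       object_width_m = 0.30,
                       distance_range_m = c(50, 150),
                       intrinsics = default_intrinsics(),
                       pose = default_pose(),
                       click_noise_px = 1.0, seed = NULL) {
  stopifnot(n_objects >= 1, object_height_m > 0,
            length(distance_range_m) == 2,
            distance_range_m[1] > 0,
            distance_range_m[2] > distance_range_m[1],
            click_noise_px >= 0)
  structure(list(n_objects = as.integer(n_objects),
                 object_height_m = object_height_m,
                 object_width_m = object_width_m,
                 distance_range_m = distance_range_m,
                 intrinsics = intrinsics, pose = pose,
                 click_noise_px = click_noise_px, seed = seed),
            class = "scene_spec")
}

#' Generate a synthetic object scene with known truth
#'
#' Places objects uniformly (by area) over the wedge of the ground plane
#' visible to the camera, intersected with the requested distance annulus;
#' projects foot (z = 0) and head (z = object height) points into the
#' image; and adds Gaussian click noise. Objects whose noiseless foot or
#' head projection falls outside the frame (5 px margin) are rejected and
#' redrawn, so all clicks lie inside the image by construction.
#'
#' @param spec a [scene_spec()].
#' @param horizon_points if > 0, also generate this many noisy clicks on
#'   the model horizon (see [generate_horizon_clicks()]).
#' @param hm a [horizon_model()] for the horizon clicks.
#' @return A list: `clicks` (a [click_set()]) and `truth` (generating pose,
#'   intrinsics, world foot/head coordinates, spec).
#' @export
generate_object_scene <- function(spec, horizon_points = 0,
                                  hm = horizon_model()) {
  stopifnot(inherits(spec, "scene_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  intr <- spec$intrinsics; pose <- spec$pose
  f <- effective_focal_length(intr)
  half_fov <- .rad2deg(atan(intr$image_width_px / (2 * f))) + 5
  n <- spec$n_objects
  margin <- 5
  w <- intr$image_width_px; h <- intr$image_height_px
  foot_w <- head_w <- matrix(NA_real_, 0, 3)
  tries <- 0
  while (nrow(foot_w) < n) {
    tries <- tries + 1
    if (tries > 200)
      stop("camera sees no ground in the requested distance range")
    m <- max(2 * (n - nrow(foot_w)), 16)
    r <- sqrt(stats::runif(m, spec$distance_range_m[1]^2,
                           spec$distance_range_m[2]^2))
    az <- .deg2rad(pose$heading_deg + stats::runif(m, -half_fov, half_fov))
    fx <- pose$pos_x_m + r * sin(az)
    fy <- pose$pos_y_m + r * cos(az)
    fw <- cbind(fx, fy, 0)
    hw <- cbind(fx, fy, spec$object_height_m)
    pf <- project(fw, intr, pose); ph <- project(hw, intr, pose)
    ok <- pf$visible & ph$visible &
      pf$uv[, 1] > margin & pf$uv[, 1] < w - margin &
      pf$uv[, 2] > margin & pf$uv[, 2] < h - margin &
      ph$uv[, 1] > margin & ph$uv[, 1] < w - margin &
      ph$uv[, 2] > margin & ph$uv[, 2] < h - margin
    foot_w <- rbind(foot_w, fw[ok, , drop = FALSE])
    head_w <- rbind(head_w, hw[ok, , drop = FALSE])
  }
  foot_w <- foot_w[seq_len(n), , drop = FALSE]
  head_w <- head_w[seq_len(n), , drop = FALSE]
  foot_uv <- project(foot_w, intr, pose)$uv
  head_uv <- project(head_w, intr, pose)$uv
  s <- spec$click_noise_px
  foot_uv <- foot_uv + matrix(stats::rnorm(2 * n, 0, s), n, 2)
  head_uv <- head_uv + matrix(stats::rnorm(2 * n, 0, s), n, 2)
  horizon_uv <- NULL
  if (horizon_points > 0)
    horizon_uv <- generate_horizon_clicks(spec, horizon_points, hm,
                                          .reseed = FALSE)
  list(clicks = click_set(foot_uv, head_uv, horizon = horizon_uv,
                          noise_px = max(s, 1e-6)),
       truth = list(pose = pose, intrinsics = intr,
                    foot_world = foot_w, head_world = head_w, spec = spec))
}

#' Generate clicks on the model horizon
#'
#' Samples points evenly along the in-image trace of the spherical-earth
#' horizon for the spec's truth camera and adds click noise.
#'
#' @param spec a [scene_spec()].
#' @param n_points number of horizon clicks (default 3, the minimum
#'   practical input).
#' @param hm a [horizon_model()].
#' @param .reseed internal: set the spec seed before drawing noise.
#' @return n x 2 matrix of pixel coordinates.
#' @export
generate_horizon_clicks <- function(spec, n_points = 3, hm = horizon_model(),
                                    .reseed = TRUE) {
  stopifnot(inherits(spec, "scene_spec"), n_points >= 1)
  if (.reseed && !is.null(spec$seed)) set.seed(spec$seed + 1L)
  tr <- horizon_in_image(spec$intrinsics, spec$pose, hm, n_points)
  if (nrow(tr) == 0)
    stop("horizon is not visible in the frame for this camera")
  tr + matrix(stats::rnorm(2 * nrow(tr), 0, spec$click_noise_px),
              nrow(tr), 2)
}

#' Generate a synthetic aerial landmark scene
#'
#' Emulates geo-referencing of near-nadir aircraft imagery: a camera high
#' above flat ground, landmark pixels scattered over the frame, exact map
#' targets obtained by backprojecting the noiseless pixels, and Gaussian
#' click noise added to the image points only.
#'
#' @param elevation_m camera height, m (default 300, a light-aircraft /
#'   helicopter altitude).
#' @param n_landmarks number of correspondences (default 8).
#' @param noise_px click noise on the image points, pixels.
#' @param seed integer seed.
#' @param intrinsics camera intrinsics.
#' @param tilt_deg,roll_deg,heading_deg,pos_x_m,pos_y_m truth pose; the
#'   default is an oblique aerial view.
#' @return A list: `landmarks` (a [landmark_set()]) and `truth` (pose,
#'   intrinsics, exact pixel positions).
#' @export
generate_landmark_scene <- function(elevation_m = 300, n_landmarks = 8,
                                    noise_px = 0.5, seed = NULL,
                                    intrinsics = default_intrinsics(),
                                    tilt_deg = 25, roll_deg = 0,
                                    heading_deg = 35,
                                    pos_x_m = 40, pos_y_m = -25) {
  if (!is.null(seed)) set.seed(seed)
  pose <- camera_pose(elevation_m, tilt_deg, roll_deg, heading_deg,
                      pos_x_m, pos_y_m)
  w <- intrinsics$image_width_px; h <- intrinsics$image_height_px
  margin <- 200
  uv <- cbind(stats::runif(n_landmarks, margin, w - margin),
              stats::runif(n_landmarks, margin, h - margin))
  targets <- backproject_to_plane(uv, intrinsics, pose)[, 1:2]
  uv_noisy <- uv + matrix(stats::rnorm(2 * n_landmarks, 0, noise_px),
                          n_landmarks, 2)
  list(landmarks = landmark_set(uv_noisy, targets),
       truth = list(pose = pose, intrinsics = intrinsics,
                    image_points = uv, noise_px = noise_px))
}

#' Generate a synthetic stereo scene
#'
#' Two cameras a known baseline apart observing a shared cloud of world
#' points; correspondences are the projections into both frames (rejecting
#' points not visible in both), with Gaussian click noise.
#'
#' @param baseline_m distance between the camera centres, m.
#' @param n_points number of correspondences.
#' @param noise_px click noise, pixels.
#' @param seed integer seed.
#' @param intrinsics shared camera intrinsics.
#' @return A list: `corr` (a [correspondence_set()] carrying the baseline
#'   as its scale constraint), `cam_a`, `cam_b` (truth cameras), and
#'   `points_world` (truth world points).
#' @export
generate_stereo_scene <- function(baseline_m = 5, n_points = 20,
                                  noise_px = 0.5, seed = NULL,
                                  intrinsics = default_intrinsics()) {
  if (!is.null(seed)) set.seed(seed)
  cam_a <- camera(intrinsics, camera_pose(12, 80, 0.5, 0))
  off <- c(0.8 * baseline_m, 0.1 * baseline_m,
           sqrt(1 - 0.8^2 - 0.1^2) * baseline_m)
  cam_b <- camera(intrinsics,
                  camera_pose(12 + off[3], 78, -1, 6,
                              pos_x_m = off[1], pos_y_m = off[2]))
  pts <- matrix(NA_real_, 0, 3)
  tries <- 0
  while (nrow(pts) < n_points) {
    tries <- tries + 1
    if (tries > 200) stop("cameras share no visible volume")
    m <- max(2 * (n_points - nrow(pts)), 16)
    cand <- cbind(stats::runif(m, -25, 25), stats::runif(m, 25, 70),
                  stats::runif(m, 0, 3))
    pa <- project(cand, cam_a$intrinsics, cam_a$pose)
    pb <- project(cand, cam_b$intrinsics, cam_b$pose)
    ok <- pa$visible & pb$visible
    pts <- rbind(pts, cand[ok, , drop = FALSE])
  }
  pts <- pts[seq_len(n_points), , drop = FALSE]
  uva <- project(pts, cam_a$intrinsics, cam_a$pose)$uv +
    matrix(stats::rnorm(2 * n_points, 0, noise_px), n_points, 2)
  uvb <- project(pts, cam_b$intrinsics, cam_b$pose)$uv +
    matrix(stats::rnorm(2 * n_points, 0, noise_px), n_points, 2)
  list(corr = correspondence_set(uva, uvb, baseline_m = baseline_m),
       cam_a = cam_a, cam_b = cam_b, points_world = pts)
}
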