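#' Stereo point correspondences
#'
#' Paired pixel annotations of the same world points in two images, plus
#' exactly one absolute-scale constraint: either the baseline distance
#' between the cameras, or the known metric distance between two of the
#' corresponded world points (e.g. foot and head of one object of known
#' size).
#'
#' @param points_a,points_b n x 2 matrices of pixel coordinates; row i of
#'   both refers to the same world point.
#' @param baseline_m distance between the two camera centres, metres.
#' @param known_size alternative constraint: list with `pair_ids` (two row
#'   indices) and `size_m`, the true distance between those two world
#'   points.
#' @return An object of class `"correspondence_set"`. Fewer than 8 pairs
#'   trigger a warning (the relative pose has 5 degrees of freedom and
#'   benefits from redundancy).
#' @export
correspondence_set <- function(points_a, points_b, baseline_m = NULL,
                               known_size = NULL) {
  points_a <- .as_points2(points_a); points_b <- .as_points2(points_b)
  if (nrow(points_a) != nrow(points_b))
    stop("points_a and points_b must be paired (equal length)")
  if (is.null(baseline_m) == is.null(known_size))
    stop("exactly one scale constraint (baseline_m or known_size) required")
  if (!is.null(baseline_m)) stopifnot(baseline_m > 0)
  if (!is.null(known_size))
    stopifnot(length(known_size$pair_ids) == 2, known_size$size_m > 0,
              all(known_size$pair_ids %in% seq_len(nrow(points_a))))
  if (nrow(points_a) < 8)
    warning("fewer than 8 correspondences; the relative-pose fit may be ",
            "poorly constrained")
  structure(list(points_a = points_a, points_b = points_b,
                 baseline_m = baseline_m, known_size = known_size),
            class = "correspondence_set")
}

#' Epipolar line of an image-A point in image B
#'
#' The locus in image B of all world points that project to `uv_a` in image
#' A. Constructed geometrically: two points along A's pixel ray are
#' projected into B and joined. The line is normalized so that
#' `a*u + b*v + c` is the signed perpendicular distance in pixels.
#'
#' @param uv_a pixel in image A (length-2).
#' @param cam_a,cam_b [camera()] objects (rectilinear projection; for the
#'   panoramic models the epipolar locus is a curve and this chord is only
#'   an approximation).
#' @param depths two depths (m along the ray) used for the construction.
#' @return Numeric `c(a, b, c)` with `a^2 + b^2 = 1`.
#' @export
epipolar_line <- function(uv_a, cam_a, cam_b, depths = c(1, 200)) {
  ca <- .camera_center(cam_a$pose); cb <- .camera_center(cam_b$pose)
  if (sqrt(sum((ca - cb)^2)) < 1e-12)
    stop("camera centres coincide: epipolar geometry undefined")
  ray <- pixel_ray(uv_a, cam_a$intrinsics, cam_a$pose)
  d <- ray$dir[1, ] / sqrt(sum(ray$dir[1, ]^2))
  pts <- rbind(ca + depths[1] * d, ca + depths[2] * d)
  pr <- project(pts, cam_b$intrinsics, cam_b$pose)
  uv <- pr$uv
  if (any(!is.finite(uv)))
    stop("ray points project behind camera B; choose different depths")
  duv <- unname(uv[2, ] - uv[1, ])
  nrm <- c(duv[2], -duv[1])
  nl <- sqrt(sum(nrm^2))
  if (nl < 1e-12) stop("degenerate epipolar construction (coincident projections)")
  nrm <- nrm / nl
  c(a = nrm[1], b = nrm[2], c = -sum(nrm * unname(uv[1, ])))
}

## Relative-pose parameter vector -> camera B, given camera A.
## Parameters: baseline direction as azimuth/inclination (degrees, in the
## world frame), and tilt/roll/heading offsets added to A's angles.
.rel_to_cam_b <- function(rel, cam_a, baseline = 1) {
  p <- as.list(rel)
  az <- .deg2rad(p$az); incl <- .deg2rad(p$incl)
  dir <- c(cos(incl) * sin(az), cos(incl) * cos(az), sin(incl))
  ca <- .camera_center(cam_a$pose)
  cb <- ca + baseline * dir
  pose_b <- structure(list(elevation_m = cb[3],
                           tilt_deg = cam_a$pose$tilt_deg + p$dtilt,
                           roll_deg = cam_a$pose$roll_deg + p$droll,
                           heading_deg = (cam_a$pose$heading_deg + p$dheading) %% 360,
                           pos_x_m = cb[1], pos_y_m = cb[2]),
                      class = "camera_pose")
  camera(cam_a$intrinsics, pose_b)   # intrinsics replaced by caller if needed
}

## distances (px) from points (n x 2) to lines (n x 3 rows a,b,c)
.point_line_dist <- function(uv, lines) {
  abs(lines[, 1] * uv[, 1] + lines[, 2] * uv[, 2] + lines[, 3])
}

## Vectorised symmetric epipolar distances for a camera pair.
.epipolar_distances <- function(cam_a, cam_b, corr) {
  ca <- .camera_center(cam_a$pose); cb <- .camera_center(cam_b$pose)
  ra <- pixel_ray(corr$points_a, cam_a$intrinsics, cam_a$pose)
  rb <- pixel_ray(corr$points_b, cam_b$intrinsics, cam_b$pose)
  line_dists <- function(origin, dirs, cam_to, uv_to) {
    n <- nrow(dirs)
    nd <- dirs / sqrt(rowSums(dirs^2))
    p1 <- sweep(nd, 2, origin, `+`)          # depth 1
    p2 <- sweep(200 * nd, 2, origin, `+`)    # depth 200
    q1 <- project(p1, cam_to$intrinsics, cam_to$pose)$uv
    q2 <- project(p2, cam_to$intrinsics, cam_to$pose)$uv
    du <- q2[, 1] - q1[, 1]; dv <- q2[, 2] - q1[, 2]
    nl <- sqrt(du^2 + dv^2)
    a <- dv / nl; b <- -du / nl
    d <- abs(a * (uv_to[, 1] - q1[, 1]) + b * (uv_to[, 2] - q1[, 2]))
    d[!is.finite(d)] <- 1e4
    d
  }
  dab <- line_dists(ca, ra$dir, cam_b, corr$points_b)
  dba <- line_dists(cb, rb$dir, cam_a, corr$points_a)
  cbind(a_to_b = dab, b_to_a = dba)
}

#' Symmetric epipolar cost of a relative camera orientation
#'
#' Mean of the point-to-epipolar-line pixel distances in both directions
#' (A-clicks to the lines induced by B-clicks and vice versa). Pixel-space
#' distances are used rather than world-space ray distances, which suffer
#' from depth-dependent scaling. The cost is scale-blind: it does not
#' depend on the baseline length, only on its direction and the relative
#' rotation.
#'
#' @param rel_params named vector `(az, incl, dtilt, droll, dheading)`:
#'   baseline direction azimuth/inclination (deg, world frame) and rotation
#'   offsets (deg) of camera B relative to camera A.
#' @param corr a [correspondence_set()].
#' @param intr_a,intr_b intrinsics of the two cameras.
#' @param cam_a optional camera A (defaults to a canonical horizontal
#'   camera at the origin; the cost only depends on relative geometry).
#' @return Mean symmetric epipolar distance, pixels.
#' @export
stereo_cost <- function(rel_params, corr, intr_a, intr_b = intr_a,
                        cam_a = NULL) {
  if (is.null(cam_a)) cam_a <- .canonical_cam_a(intr_a)
  cam_b <- .rel_to_cam_b(rel_params, cam_a)
  cam_b$intrinsics <- intr_b
  d <- .epipolar_distances(cam_a, cam_b, corr)
  mean(d)
}

.canonical_cam_a <- function(intr_a) {
  camera(intr_a, structure(list(elevation_m = 0, tilt_deg = 90, roll_deg = 0,
                                heading_deg = 0, pos_x_m = 0, pos_y_m = 0),
                           class = "camera_pose"))
}

#' Triangulate corresponding pixels from two cameras
#'
#' Returns the midpoint of the common perpendicular of the two pixel rays
#' for each correspondence, with the perpendicular gap as a quality
#' measure. Near-parallel ray pairs are flagged low-confidence.
#'
#' @param uv_a,uv_b n x 2 pixel matrices (paired).
#' @param cam_a,cam_b [camera()] objects.
#' @param min_angle_deg rays intersecting at less than this angle are
#'   flagged.
#' @return A list: `points` (n x 3 world coordinates, m), `gap_m` (common
#'   perpendicular length), `low_confidence` (logical).
#' @export
triangulate <- function(uv_a, uv_b, cam_a, cam_b, min_angle_deg = 0.1) {
  ra <- pixel_ray(uv_a, cam_a$intrinsics, cam_a$pose)
  rb <- pixel_ray(uv_b, cam_b$intrinsics, cam_b$pose)
  da <- ra$dir / sqrt(rowSums(ra$dir^2))
  db <- rb$dir / sqrt(rowSums(rb$dir^2))
  oa <- ra$origin; ob <- rb$origin
  w0 <- matrix(oa - ob, nrow(da), 3, byrow = TRUE)
  b <- rowSums(da * db)
  d1 <- rowSums(da * w0)
  e1 <- rowSums(db * w0)
  denom <- 1 - b^2
  s <- (b * e1 - d1) / denom            # along ray A
  t <- (e1 - b * d1) / denom            # along ray B
  pa <- sweep(s * da, 2, oa, `+`)
  pb <- sweep(t * db, 2, ob, `+`)
  gap <- sqrt(rowSums((pa - pb)^2))
  ang <- .rad2deg(acos(pmin(1, pmax(-1, abs(b)))))
  low <- !is.finite(s) | !is.finite(t) | ang < min_angle_deg
  pts <- (pa + pb) / 2
  dimnames(pts) <- list(NULL, c("x_m", "y_m", "z_m"))
  list(points = pts, gap_m = unname(gap), low_confidence = unname(low))
}

#' Fit the relative orientation of two cameras from correspondences
#'
#' Metropolis Monte-Carlo estimation of the 5 scale-free relative-pose
#' parameters (baseline direction azimuth + inclination, and tilt/roll/
#' heading offsets of camera B) by minimizing the symmetric epipolar pixel
#' distances, preceded by a multi-start mode search. The absolute scale is
#' fixed afterwards from the correspondence set's constraint (baseline
#' length, or one known object size via triangulation). A chirality check
#' (triangulated points must lie in front of both cameras) resolves the
#' mirror ambiguity of the epipolar cost.
#'
#' @param corr a [correspondence_set()] with a scale constraint.
#' @param intr_a,intr_b camera intrinsics.
#' @param cam_a optional known camera A (pose defaults to canonical:
#'   origin, horizontal, heading 0); the fit is relative so any choice
#'   works.
#' @param noise_px pixel noise scale converting cost to log-likelihood.
#' @param n_iter total Metropolis iterations (20% burn-in discarded).
#' @param seed integer seed.
#' @param init optional named start `(az, incl, dtilt, droll, dheading)`.
#' @return A `"chain_summary"` over the 5 relative parameters with extra
#'   elements: `baseline_m` (fitted scale), `cam_b` (the posterior-mean
#'   camera B at that scale), `cam_a`, and `cost_px` (mean symmetric
#'   epipolar distance at the posterior mean).
#' @export
fit_relative_orientation <- function(corr, intr_a, intr_b = intr_a,
                                     cam_a = NULL, noise_px = 1,
                                     n_iter = 10000, seed = NULL,
                                     init = NULL) {
  stopifnot(inherits(corr, "correspondence_set"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cam_a)) cam_a <- .canonical_cam_a(intr_a)
  par_names <- c("az", "incl", "dtilt", "droll", "dheading")
  lo <- c(-360, -89, -90, -90, -180)
  hi <- c(720, 89, 90, 90, 180)
  n <- nrow(corr$points_a)
  make_cam_b <- function(p, baseline = 1) {
    cb <- .rel_to_cam_b(p, cam_a, baseline); cb$intrinsics <- intr_b; cb
  }
  loglik <- function(p) {
    if (any(p < lo) || any(p > hi)) return(-Inf)
    cam_b <- make_cam_b(p)
    d <- .epipolar_distances(cam_a, cam_b, corr)
    ll <- -sum(d^2) / (2 * noise_px^2)
    ## chirality: penalise points behind either camera
    tri <- triangulate(corr$points_a, corr$points_b, cam_a, cam_b)
    za <- world_to_camera(tri$points, cam_a$pose)[, 3]
    zb <- world_to_camera(tri$points, cam_b$pose)[, 3]
    ll - 1e3 * sum(za <= 0 | zb <= 0)
  }
  ## pure epipolar objective for the mode search (the chirality term only
  ## separates the mirror solutions; it is applied when ranking the optima)
  epi_ll <- function(p) {
    if (any(p < lo) || any(p > hi)) return(-Inf)
    d <- .epipolar_distances(cam_a, make_cam_b(p), corr)
    -sum(d^2) / (2 * noise_px^2)
  }
  draw_init <- function()
    stats::setNames(c(stats::runif(1, 0, 360), stats::runif(1, -60, 60),
                      stats::runif(3, -20, 20)), par_names)
  if (is.null(init)) init <- draw_init()
  else init <- stats::setNames(as.numeric(init), par_names)
  cand <- lapply(seq_len(12), function(k) {
    s <- if (k == 1) init else draw_init()
    .mode_search(epi_ll, stats::setNames(s, par_names), draw_init,
                 n_starts = 1, lo = lo, hi = hi)
  })
  init <- cand[[which.max(vapply(cand, loglik, numeric(1)))]]
  ## polish the selected mode before sampling
  polish <- try(stats::optim(init, function(p) {
    v <- loglik(stats::setNames(pmin(pmax(p, lo), hi), par_names))
    if (is.finite(v)) -v else 1e12
  }, method = "Nelder-Mead", control = list(maxit = 1500, reltol = 1e-12)),
  silent = TRUE)
  if (!inherits(polish, "try-error"))
    init <- stats::setNames(pmin(pmax(polish$par, lo), hi), par_names)
  scales <- c(0.5, 0.5, 0.1, 0.1, 0.5)
  ch <- metropolis_sample(loglik, init, scales, n_iter = n_iter, seed = NULL)
  samples <- ch$samples
  samples[, "az"] <- samples[, "az"] %% 360
  out <- chain_summary(samples, acceptance_rate = ch$acceptance_rate,
                       seed = seed, proposal_scales = ch$proposal_scales)
  pm <- stats::setNames(out$mean, par_names)
  ## fix the absolute scale
  if (!is.null(corr$baseline_m)) {
    baseline <- corr$baseline_m
  } else {
    ks <- corr$known_size
    cam_b1 <- make_cam_b(pm, baseline = 1)
    tri <- triangulate(corr$points_a[ks$pair_ids, , drop = FALSE],
                       corr$points_b[ks$pair_ids, , drop = FALSE],
                       cam_a, cam_b1)
    measured <- sqrt(sum((tri$points[1, ] - tri$points[2, ])^2))
    if (!is.finite(measured) || measured <= 0)
      stop("known-size pair could not be triangulated at unit baseline")
    baseline <- ks$size_m / measured
  }
  out$baseline_m <- baseline
  out$cam_a <- cam_a
  out$cam_b <- make_cam_b(pm, baseline = baseline)
  out$cost_px <- stereo_cost(pm, corr, intr_a, intr_b, cam_a = cam_a)
  out
}
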