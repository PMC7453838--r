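#' Click annotations for object-height fitting
#'
#' Paired base (foot) and top (head) pixel positions of objects of roughly
#' known height, plus optional clicks on the visible horizon.
#'
#' @param foot,head n x 2 matrices (or length-2 vectors) of pixel
#'   coordinates; row i of `head` is the top of the object whose base is
#'   row i of `foot`.
#' @param horizon optional m x 2 matrix of pixel points on the horizon.
#' @param noise_px assumed click noise scale in pixels (Gaussian, isotropic).
#' @return An object of class `"click_set"`.
#' @export
click_set <- function(foot, head, horizon = NULL, noise_px = 1) {
  foot <- .as_points2(foot); head <- .as_points2(head)
  if (nrow(foot) != nrow(head) || nrow(foot) < 1)
    stop("foot and head must be non-empty paired lists of equal length")
  if (!all(is.finite(foot)) || !all(is.finite(head)))
    stop("click coordinates must be finite")
  if (!is.null(horizon)) {
    horizon <- .as_points2(horizon)
    if (!all(is.finite(horizon))) stop("horizon clicks must be finite")
  }
  structure(list(foot = foot, head = head, horizon = horizon,
                 noise_px = noise_px), class = "click_set")
}

#' @export
print.click_set <- function(x, ...) {
  cat(sprintf("Click set: %d foot/head pairs, %d horizon points (noise %.2g px)\n",
              nrow(x$foot), if (is.null(x$horizon)) 0L else nrow(x$horizon),
              x$noise_px))
  invisible(x)
}

#' Prior distribution of object heights
#'
#' The only informative prior of the object-height fit: what is known about
#' the true heights of the clicked objects (e.g. adult animals of a species
#' have height 0.75 m give or take a few cm). The spread may be a known
#' number, or `"free"` to estimate it from the data as an extra sampled
#' parameter (in log-space, to keep it positive). Non-Gaussian knowledge can
#' be supplied as a custom log-density.
#'
#' @param mean_m mean object height, m (> 0).
#' @param sd_m standard deviation in m, or the string `"free"`.
#' @param logdensity optional function `f(heights_m, sd_m)` returning the
#'   log-density of each height, overriding the normal model.
#' @return An object of class `"height_prior"`.
#' @export
height_prior <- function(mean_m, sd_m = "free", logdensity = NULL) {
  stopifnot(is.numeric(mean_m), mean_m > 0)
  free <- identical(sd_m, "free")
  if (!free) stopifnot(is.numeric(sd_m), sd_m > 0)
  structure(list(mean_m = mean_m, sd_m = if (free) NA_real_ else sd_m,
                 free_sd = free, logdensity = logdensity),
            class = "height_prior")
}

.height_logdens <- function(h, prior, sd) {
  if (!is.null(prior$logdensity)) prior$logdensity(h, sd)
  else stats::dnorm(h, prior$mean_m, sd, log = TRUE)
}

## Accept a camera_pose or a named numeric vector for likelihood params.
.params_to_pose <- function(params) {
  if (inherits(params, "camera_pose")) return(params)
  p <- as.list(params)
  pick <- function(...) {
    for (nm in c(...)) if (!is.null(p[[nm]])) return(p[[nm]])
    NULL
  }
  structure(list(elevation_m = pick("elevation_m", "elevation"),
                 tilt_deg = pick("tilt_deg", "tilt"),
                 roll_deg = pick("roll_deg", "roll") %||% 0,
                 heading_deg = pick("heading_deg", "heading") %||% 0,
                 pos_x_m = pick("pos_x_m", "pos_x") %||% 0,
                 pos_y_m = pick("pos_y_m", "pos_y") %||% 0),
            class = "camera_pose")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log-likelihood of extrinsic parameters given foot/head clicks
#'
#' For each foot/head pair: the foot pixel is backprojected onto the ground
#' plane (z = 0), the head pixel is backprojected under the constraint that
#' it lies vertically above the foot, and the resulting object height is
#' scored under the height prior. Pairs whose foot pixel lies above the
#' model horizon (so its ray never reaches the ground of a spherical earth)
#' contribute `-Inf`; the sampler then rejects such poses rather than
#' erroring.
#'
#' @param params a [camera_pose()] or named numeric vector with elements
#'   `elevation` (m), `tilt`, `roll` (degrees); optionally `log_sd` when the
#'   prior spread is free.
#' @param clicks a [click_set()].
#' @param prior a [height_prior()].
#' @param intr a [camera_intrinsics()].
#' @param hm a [horizon_model()] used for the above-horizon feasibility cut.
#' @return A single log-probability (may be `-Inf`, never an error for
#'   infeasible geometry).
#' @export
object_height_loglik <- function(params, clicks, prior, intr,
                                 hm = horizon_model()) {
  pose <- .params_to_pose(params)
  if (is.null(pose$elevation_m) || pose$elevation_m <= 0) return(-Inf)
  sd <- if (prior$free_sd) {
    ls <- as.list(params)$log_sd
    if (is.null(ls) || !is.finite(ls))
      stop("prior sd is free: params must include log_sd")
    exp(ls)
  } else prior$sd_m
  heights <- .object_heights(pose, clicks, intr, hm)
  if (is.null(heights)) return(-Inf)
  sum(.height_logdens(heights, prior, sd))
}

## Estimated object heights for a pose, or NULL when any pair is infeasible
## (foot above the model horizon, or degenerate head geometry).
.object_heights <- function(pose, clicks, intr, hm) {
  ray <- pixel_ray(clicks$foot, intr, pose)
  dz <- ray$dir[, 3] / sqrt(rowSums(ray$dir^2))
  dip <- .deg2rad(horizon_dip(pose$elevation_m, hm))
  if (any(dz >= -sin(dip))) return(NULL)   # foot above model horizon
  tt <- -ray$origin[3] / ray$dir[, 3]
  foot_world <- cbind(ray$origin[1] + tt * ray$dir[, 1],
                      ray$origin[2] + tt * ray$dir[, 2], 0)
  head_world <- backproject_with_foot_constraint(clicks$head, foot_world,
                                                 intr, pose,
                                                 allow_miss = TRUE)
  heights <- head_world[, 3]
  if (any(!is.finite(heights))) return(NULL)
  heights
}

#' Log-likelihood of extrinsic parameters given horizon clicks
#'
#' Gaussian penalty on the perpendicular pixel distance from each clicked
#' horizon point to the spherical-earth horizon trace implied by the pose.
#' If the model horizon does not project in front of the camera at all, a
#' large finite penalty is returned (not `-Inf`), keeping the sampler
#' mobile.
#'
#' @param params as in [object_height_loglik()].
#' @param horizon_clicks m x 2 matrix of clicked horizon pixels.
#' @param intr a [camera_intrinsics()].
#' @param hm a [horizon_model()].
#' @param noise_px click noise scale, pixels.
#' @return A single log-probability.
#' @export
horizon_loglik <- function(params, horizon_clicks, intr,
                           hm = horizon_model(), noise_px = 1) {
  pose <- .params_to_pose(params)
  if (is.null(pose$elevation_m) || pose$elevation_m <= 0) return(-Inf)
  d <- .horizon_distances(horizon_clicks, intr, pose, hm)
  if (is.null(d)) d <- rep(1e4, nrow(.as_points2(horizon_clicks)))
  sum(stats::dnorm(d, 0, noise_px, log = TRUE))
}

#' Fit extrinsic camera parameters from object clicks
#'
#' Metropolis Monte-Carlo estimation of camera elevation, tilt and roll
#' (and, when the height-prior spread is free, the object-height sd) from
#' foot/head click pairs, optionally constrained by clicked horizon points.
#' Heading and position are irrelevant for this fit and fixed at 0. The
#' chain is preceded (by default) by a short multi-start Nelder-Mead search
#' for the posterior mode, which makes convergence at typical chain lengths
#' independent of the random starting point; set `optimize_start = FALSE`
#' for a pure random initialization.
#'
#' @param clicks a [click_set()]; its `horizon` points are used when
#'   `use_horizon = TRUE`.
#' @param intr a [camera_intrinsics()].
#' @param prior a [height_prior()]; default `height_prior(0.75, "free")`.
#' @param use_horizon include the horizon term when horizon clicks exist.
#' @param n_iter total Metropolis iterations (20% burn-in discarded).
#' @param seed integer seed for reproducibility.
#' @param init optional named start vector `(elevation, tilt, roll[,
#'   log_sd])`; otherwise drawn from broad uniform ranges (elevation
#'   1–100 m, tilt 30–120 deg, roll ±10 deg), restarting up to 10 times if
#'   the likelihood is impossible there.
#' @param optimize_start precede sampling by a mode search (default TRUE).
#' @param proposal_scales proposal sds for (elevation m, tilt deg, roll deg,
#'   log_sd); adapted during burn-in toward 20–40% acceptance.
#' @param ranges named list of flat-prior support intervals.
#' @param hm a [horizon_model()].
#' @return A `"chain_summary"` over parameters `elevation_m`, `tilt_deg`,
#'   `roll_deg` (and `height_sd_m` when free), with an extra element `wide`
#'   flagging an under-constrained, wide posterior.
#' @export
fit_extrinsics <- function(clicks, intr, prior = height_prior(0.75, "free"),
                           use_horizon = TRUE, n_iter = 10000, seed = NULL,
                           init = NULL, optimize_start = TRUE,
                           proposal_scales = c(0.5, 0.5, 0.5, 0.05),
                           ranges = list(elevation = c(1, 100),
                                         tilt = c(30, 120),
                                         roll = c(-10, 10),
                                         log_sd = log(c(1e-3, 1))),
                           hm = horizon_model()) {
  stopifnot(inherits(clicks, "click_set"), inherits(prior, "height_prior"))
  if (!is.null(seed)) set.seed(seed)
  horizon_uv <- if (use_horizon) clicks$horizon else NULL
  free <- prior$free_sd
  par_names <- c("elevation", "tilt", "roll", if (free) "log_sd")
  lo <- vapply(ranges[par_names], `[`, numeric(1), 1)
  hi <- vapply(ranges[par_names], `[`, numeric(1), 2)
  loglik <- function(p) {
    if (any(p < lo) || any(p > hi)) return(-Inf)
    ll <- object_height_loglik(p, clicks, prior, intr, hm)
    if (!is.finite(ll)) return(-Inf)
    if (!is.null(horizon_uv))
      ll <- ll + horizon_loglik(p, horizon_uv, intr, hm,
                                noise_px = clicks$noise_px)
    ll
  }
  ## pose-only likelihood with the height spread profiled out (its ML value
  ## given the pose); keeps the start search low-dimensional and well-behaved
  prof_sd <- function(h) max(sqrt(mean((h - prior$mean_m)^2)), 1.5e-3)
  prof_loglik <- function(p3) {
    if (any(p3 < lo[1:3]) || any(p3 > hi[1:3])) return(-Inf)
    pose <- .params_to_pose(p3)
    h <- .object_heights(pose, clicks, intr, hm)
    if (is.null(h)) return(-Inf)
    sdh <- if (free) prof_sd(h) else prior$sd_m
    ll <- sum(.height_logdens(h, prior, sdh))
    if (!is.null(horizon_uv))
      ll <- ll + horizon_loglik(p3, horizon_uv, intr, hm,
                                noise_px = clicks$noise_px)
    ll
  }
  draw_init3 <- function() stats::setNames(lo[1:3] + stats::runif(3) *
                                             (hi[1:3] - lo[1:3]),
                                           par_names[1:3])
  add_log_sd <- function(p3) {
    if (!free) return(p3)
    h <- .object_heights(.params_to_pose(p3), clicks, intr, hm)
    ls <- if (is.null(h)) log(0.1) else log(prof_sd(h))
    c(p3, log_sd = min(max(ls, lo[4]), hi[4]))
  }
  if (is.null(init)) {
    for (i in 1:10) {
      init3 <- draw_init3()
      if (is.finite(prof_loglik(init3))) break
      if (i == 10) stop("no feasible random starting point found in 10 tries")
    }
  } else {
    init <- stats::setNames(as.numeric(init), par_names)
    init3 <- init[1:3]
  }
  if (optimize_start) {
    extra <- NULL
    if (!is.null(horizon_uv) && nrow(horizon_uv) >= 2) {
      ## the clicked horizon almost fixes tilt and roll for any elevation:
      ## seed the search along that curve at log-spaced elevations
      extra <- lapply(c(2, 4, 8, 16, 32, 64), function(e) {
        tr <- .horizon_pose_guess(horizon_uv, intr, e, hm)
        stats::setNames(c(e, tr), par_names[1:3])
      })
    }
    init3 <- .mode_search(prof_loglik, init3, draw_init3, n_starts = 6,
                          lo = lo[1:3], hi = hi[1:3], extra_starts = extra)
  }
  init <- if (is.null(init) || optimize_start) add_log_sd(init3) else init
  ch <- metropolis_sample(loglik, init,
                          rep_len(proposal_scales, length(par_names)),
                          n_iter = n_iter, seed = NULL)
  samples <- ch$samples
  colnames(samples) <- c("elevation_m", "tilt_deg", "roll_deg",
                         if (free) "height_sd_m")
  if (free) samples[, "height_sd_m"] <- exp(samples[, "height_sd_m"])
  out <- chain_summary(samples, acceptance_rate = ch$acceptance_rate,
                       seed = seed, proposal_scales = ch$proposal_scales)
  out$wide <- unname(out$sd["tilt_deg"] > 5 |
                       out$sd["elevation_m"] / out$mean["elevation_m"] > 0.5)
  if (out$wide)
    message("posterior is wide: the configuration is weakly constrained ",
            "(few objects and/or no horizon)")
  out
}

## Tilt and roll implied by clicked horizon points for a given elevation
## (rectilinear geometry): roll from the line's slope, tilt from the line's
## height at the image centre and the spherical-earth dip.
.horizon_pose_guess <- function(horizon_uv, intr, elevation_m,
                                hm = horizon_model()) {
  uv <- .as_points2(horizon_uv)
  f <- effective_focal_length(intr)
  slope <- if (nrow(uv) >= 2 && diff(range(uv[, 1])) > 1e-9)
    stats::coef(stats::lm(uv[, 2] ~ uv[, 1]))[[2]] else 0
  roll <- -.rad2deg(atan(slope))
  v_ctr <- mean(uv[, 2] + slope * (intr$image_width_px / 2 - uv[, 1]))
  dip <- horizon_dip(elevation_m, hm)
  tilt <- 90 - dip + .rad2deg(atan((v_ctr - intr$image_height_px / 2) / f))
  c(tilt = tilt, roll = roll)
}

## Multi-start Nelder-Mead maximisation of a log-likelihood, clamped to the
## support box. Used to place the Metropolis chain at the posterior mode.
.mode_search <- function(loglik, init, draw_init, n_starts, lo, hi,
                         free_extra = NULL, extra_starts = NULL) {
  negll <- function(p) {
    v <- loglik(stats::setNames(pmin(pmax(p, lo), hi), names(init)))
    if (is.finite(v)) -v else 1e12
  }
  best <- init; best_val <- negll(init)
  starts <- list(init)
  for (k in seq_len(n_starts - 1)) {
    s <- draw_init()
    if (!is.null(free_extra)) s[names(free_extra)] <- free_extra
    starts[[k + 1]] <- s
  }
  starts <- c(starts, extra_starts)
  for (s in starts) {
    opt <- try({
      o <- stats::optim(s, negll, method = "Nelder-Mead",
                        control = list(maxit = 400))
      ## restart once from the result: Nelder-Mead routinely stalls with a
      ## collapsed simplex on curved ridges
      stats::optim(o$par, negll, method = "Nelder-Mead",
                   control = list(maxit = 400))
    }, silent = TRUE)
    if (!inherits(opt, "try-error") && opt$value < best_val) {
      best <- pmin(pmax(opt$par, lo), hi); best_val <- opt$value
    }
  }
  stats::setNames(best, names(init))
}
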