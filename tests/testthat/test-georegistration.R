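test_that("local tangent conversion matches closed forms and round-trips", {
  expect_equal(latlon_to_local(47.1, 11.3, 47.1, 11.3)[1, ],
               c(x_m = 0, y_m = 0))
  # one degree of latitude = pi R / 180
  expect_equal(latlon_to_local(48.1, 11.3, 47.1, 11.3)[1, "y_m"],
               c(y_m = 111194.9), tolerance = 1e-6)
  set.seed(61)
  lat <- runif(100, -60, 60); lon <- runif(100, -170, 170)
  xy <- latlon_to_local(lat, lon, 12.3, 45.6)
  back <- local_to_latlon(xy[, 1], xy[, 2], 12.3, 45.6)
  expect_lt(max(abs(back[, "lat"] - lat)), 1e-9)
  expect_lt(max(abs(back[, "lon"] - lon)), 1e-9)
})

test_that("landmark sets are validated", {
  expect_error(landmark_set(matrix(1, 2, 2), matrix(1, 2, 2)), "at least 3")
  expect_error(landmark_set(matrix(1, 3, 2), matrix(1, 4, 2)), "paired")
  collinear <- cbind(1:4, 2 * (1:4))
  expect_warning(landmark_set(matrix(runif(8, 0, 100), 4, 2), collinear),
                 "collinear")
})

test_that("registration cost: zero at truth, rigid offsets, penalties", {
  sc <- generate_landmark_scene(noise_px = 0, seed = 62)
  tp <- sc$truth$pose
  truth <- c(elevation = tp$elevation_m, tilt = tp$tilt_deg,
             pos_x = tp$pos_x_m, pos_y = tp$pos_y_m,
             heading = tp$heading_deg)
  intr <- sc$truth$intrinsics
  expect_lt(registration_cost(truth, sc$landmarks, intr), 1e-9)
  shifted <- landmark_set(sc$landmarks$image_points,
                          sweep(sc$landmarks$target_points, 2, c(1, 0), `+`))
  expect_equal(registration_cost(truth, shifted, intr), 1, tolerance = 1e-9)
  # common translation of camera and targets leaves the cost unchanged
  moved <- landmark_set(sc$landmarks$image_points,
                        sweep(sc$landmarks$target_points, 2, c(50, -20), `+`))
  truth_moved <- truth + c(0, 0, 50, -20, 0)
  expect_lt(registration_cost(truth_moved, moved, intr), 1e-9)
  # camera pointing away from every landmark: large finite penalty
  bad <- truth; bad["tilt"] <- 95
  expect_gte(registration_cost(bad, sc$landmarks, intr), 1e6)
})

test_that("noiseless landmarks are recovered exactly after refinement", {
  sc <- generate_landmark_scene(noise_px = 0, seed = 63)
  fit <- fit_georeference(sc$landmarks, sc$truth$intrinsics,
                          n_iter = 5000, seed = 1)
  tp <- sc$truth$pose
  truth <- c(tp$elevation_m, tp$tilt_deg, tp$pos_x_m, tp$pos_y_m,
             tp$heading_deg)
  expect_lt(max(abs(fit$refined - truth)), 1e-3)
  expect_lt(fit$refined_cost, 1e-6)
})

test_that("noisy aerial scene: sub-metre registration, truth inside posterior", {
  sc <- generate_landmark_scene(elevation_m = 300, n_landmarks = 8,
                                noise_px = 0.5, seed = 64)
  fit <- fit_georeference(sc$landmarks, sc$truth$intrinsics,
                          n_iter = 8000, seed = 2)
  expect_lt(fit$refined_cost, 1)
  tp <- sc$truth$pose
  truth <- c(tp$elevation_m, tp$tilt_deg, tp$pos_x_m, tp$pos_y_m,
             tp$heading_deg)
  z <- abs(fit$mean - truth) / fit$sd
  expect_true(all(z < 3))
})

test_that("dropping a landmark keeps the fit working but widens it", {
  # single-chain sd estimates are noisy near the minimal configuration, so
  # compare the typical (median over replicates) posterior-width ratio
  ratios <- sapply(1:4, function(r) {
    sc <- generate_landmark_scene(n_landmarks = 4, noise_px = 0.5,
                                  seed = 60 + r)
    fit4 <- fit_georeference(sc$landmarks, sc$truth$intrinsics,
                             n_iter = 6000, seed = r)
    lm3 <- suppressWarnings(
      landmark_set(sc$landmarks$image_points[1:3, ],
                   sc$landmarks$target_points[1:3, ]))
    fit3 <- fit_georeference(lm3, sc$truth$intrinsics, n_iter = 6000,
                             seed = r)
    exp(mean(log(fit3$sd / fit4$sd)))
  })
  expect_gt(median(ratios), 1)
})

test_that("wider landmark spread pins the heading more tightly", {
  base <- generate_landmark_scene(n_landmarks = 8, noise_px = 0.5, seed = 66)
  # shrink the image spread of the same scene toward its centroid
  ip <- base$landmarks$image_points
  ctr <- colMeans(ip)
  ip_small <- sweep(sweep(ip, 2, ctr), 1:2, 0.25, `*`)
  ip_small <- sweep(ip_small, 2, ctr, `+`)
  tgt_small <- backproject_to_plane(ip_small, base$truth$intrinsics,
                                    base$truth$pose)[, 1:2]
  lm_small <- landmark_set(ip_small, tgt_small)
  fit_wide <- fit_georeference(base$landmarks, base$truth$intrinsics,
                               n_iter = 6000, seed = 4)
  fit_small <- fit_georeference(lm_small, base$truth$intrinsics,
                                n_iter = 6000, seed = 4)
  expect_gt(fit_small$sd["heading_deg"], fit_wide$sd["heading_deg"])
})
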