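test_that("epipolar lines pass through corresponding points (noiseless)", {
  sc <- generate_stereo_scene(n_points = 20, noise_px = 0, seed = 71)
  for (i in c(1, 7, 20)) {
    l <- epipolar_line(sc$corr$points_a[i, ], sc$cam_a, sc$cam_b)
    d <- abs(sum(l[1:2] * sc$corr$points_b[i, ]) + l[3])
    expect_lt(d, 1e-8)
  }
  expect_error(epipolar_line(c(1, 1), sc$cam_a, sc$cam_a), "coincide")
})

test_that("rectified stereo pair yields horizontal epipolar lines", {
  intr <- default_intrinsics()
  cam_a <- camera(intr, camera_pose(10, 90, 0, 0, 0, 0))
  cam_b <- camera(intr, camera_pose(10, 90, 0, 0, 1, 0))  # pure x baseline
  for (uv in list(c(1000, 800), c(2304, 1296), c(4000, 2000))) {
    l <- epipolar_line(uv, cam_a, cam_b)
    # line v = const: normal (0, 1) up to sign, at the same row
    expect_lt(abs(l[["a"]]), 1e-9)
    expect_lt(abs(l[["b"]] * uv[2] + l[["c"]]), 1e-6)
  }
})

test_that("geometric epipolar distances match the fundamental-matrix oracle", {
  sc <- generate_stereo_scene(n_points = 20, noise_px = 1, seed = 72)
  d_oracle <- fmatrix_distances(sc$cam_a, sc$cam_b,
                                sc$corr$points_a, sc$corr$points_b)
  d_geom <- vapply(seq_len(20), function(i) {
    l <- epipolar_line(sc$corr$points_a[i, ], sc$cam_a, sc$cam_b)
    abs(sum(l[1:2] * sc$corr$points_b[i, ]) + l[3])
  }, numeric(1))
  expect_lt(max(abs(d_geom - d_oracle)), 1e-6)
})

test_that("stereo cost is zero at truth, positive with noise or perturbation", {
  sc0 <- generate_stereo_scene(n_points = 20, noise_px = 0, seed = 73)
  rel <- true_rel_params(sc0$cam_a, sc0$cam_b)
  intr <- sc0$cam_a$intrinsics
  expect_lt(stereo_cost(rel, sc0$corr, intr, cam_a = sc0$cam_a), 1e-8)
  scn <- generate_stereo_scene(n_points = 20, noise_px = 1, seed = 73)
  c_truth <- stereo_cost(rel, scn$corr, intr, cam_a = scn$cam_a)
  expect_gt(c_truth, 0)
  expect_lt(c_truth, 5)     # O(1 px) for 1 px click noise
  for (k in 1:5) {
    pert <- rel + c(0, 0, 1, 0, 0) * (k == 1) + c(0, 0, 0, 1, 0) * (k == 2) +
      c(0, 0, 0, 0, 1) * (k == 3) + c(2, 0, 0, 0, 0) * (k == 4) +
      c(0, 2, 0, 0, 0) * (k == 5)
    expect_gt(stereo_cost(pert, scn$corr, intr, cam_a = scn$cam_a), c_truth)
  }
})

test_that("triangulation inverts the projection and is camera-symmetric", {
  sc <- generate_stereo_scene(n_points = 20, noise_px = 0, seed = 74)
  tri <- triangulate(sc$corr$points_a, sc$corr$points_b, sc$cam_a, sc$cam_b)
  expect_lt(max(abs(tri$points - sc$points_world)), 1e-8)
  expect_lt(max(tri$gap_m), 1e-8)
  swapped <- triangulate(sc$corr$points_b, sc$corr$points_a,
                         sc$cam_b, sc$cam_a)
  expect_equal(swapped$points, tri$points, tolerance = 1e-9)
  # a 0.75 m object seen by both cameras triangulates to its true height
  foot <- c(2, 40, 0); head <- c(2, 40, 0.75)
  uva <- project(rbind(foot, head), sc$cam_a$intrinsics, sc$cam_a$pose)$uv
  uvb <- project(rbind(foot, head), sc$cam_b$intrinsics, sc$cam_b$pose)$uv
  t2 <- triangulate(uva, uvb, sc$cam_a, sc$cam_b)
  expect_equal(unname(t2$points[2, 3] - t2$points[1, 3]), 0.75,
               tolerance = 1e-8)
})

test_that("relative orientation is recovered from noisy correspondences", {
  errs <- sapply(1:3, function(s) {
    sc <- generate_stereo_scene(baseline_m = 5, n_points = 20,
                                noise_px = 0.5, seed = 80 + s)
    fit <- fit_relative_orientation(sc$corr, sc$cam_a$intrinsics,
                                    cam_a = sc$cam_a, n_iter = 5000,
                                    seed = s)
    pb <- fit$cam_b$pose; tb <- sc$cam_b$pose
    c(rot = max(abs(c(pb$tilt_deg - tb$tilt_deg, pb$roll_deg - tb$roll_deg,
                      pb$heading_deg - tb$heading_deg))),
      base = abs(fit$baseline_m - 5) / 5,
      pos = sqrt(sum((c(pb$pos_x_m, pb$pos_y_m, pb$elevation_m) -
                        c(tb$pos_x_m, tb$pos_y_m, tb$elevation_m))^2)))
  })
  expect_lt(max(errs["rot", ]), 0.5)
  expect_lt(max(errs["pos", ]), 0.05 * 5)
})

test_that("one known object size fixes the scale like the baseline does", {
  sc <- generate_stereo_scene(baseline_m = 5, n_points = 20,
                              noise_px = 0.5, seed = 85)
  # the known object spans two well-separated scene points, so its
  # triangulated length is insensitive to per-point depth noise
  D <- as.matrix(dist(sc$points_world))
  ij <- which(D == max(D), arr.ind = TRUE)[1, ]
  size <- D[ij[1], ij[2]]
  corr_ks <- correspondence_set(sc$corr$points_a, sc$corr$points_b,
                                known_size = list(pair_ids = unname(ij),
                                                  size_m = size))
  fit <- fit_relative_orientation(corr_ks, sc$cam_a$intrinsics,
                                  cam_a = sc$cam_a, n_iter = 5000, seed = 5)
  expect_lt(abs(fit$baseline_m - 5) / 5, 0.02)
})

test_that("swapping the two cameras recovers the inverse relative pose", {
  sc <- generate_stereo_scene(baseline_m = 5, n_points = 20,
                              noise_px = 0.3, seed = 86)
  fit_ab <- fit_relative_orientation(sc$corr, sc$cam_a$intrinsics,
                                     cam_a = sc$cam_a, n_iter = 4000, seed = 6)
  corr_ba <- correspondence_set(sc$corr$points_b, sc$corr$points_a,
                                baseline_m = 5)
  fit_ba <- fit_relative_orientation(corr_ba, sc$cam_b$intrinsics,
                                     cam_a = sc$cam_b, n_iter = 4000, seed = 6)
  R_ab <- pose_rotation(fit_ab$cam_b$pose) %*% t(pose_rotation(fit_ab$cam_a$pose))
  R_ba <- pose_rotation(fit_ba$cam_b$pose) %*% t(pose_rotation(fit_ba$cam_a$pose))
  # the two relative rotations should be (near) inverses
  resid <- R_ab %*% R_ba
  ang <- acos(pmin(1, (sum(diag(resid)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 1)
})

test_that("correspondence sets enforce exactly one scale constraint", {
  pts <- matrix(runif(40, 0, 100), 20, 2)
  expect_error(correspondence_set(pts, pts), "exactly one")
  expect_error(correspondence_set(pts, pts, baseline_m = 5,
                                  known_size = list(pair_ids = c(1, 2),
                                                    size_m = 1)),
               "exactly one")
  expect_warning(correspondence_set(pts[1:5, ], pts[1:5, ], baseline_m = 5),
                 "fewer than 8")
})
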