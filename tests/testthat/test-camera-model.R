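test_that("effective focal length rescales mm to pixels", {
  intr <- camera_intrinsics(14, 17.3, 9.7, 4608, 2592)
  # 14 * 4608 / 17.3, frozen from direct evaluation
  expect_equal(effective_focal_length(intr), 3729.017341, tolerance = 1e-9)
  expect_equal(effective_focal_length(camera_intrinsics(1, 1, 1, 1000, 1000)),
               1000)
  intr2 <- camera_intrinsics(14, 17.3, 9.7, 2 * 4608, 2 * 2592)
  expect_equal(effective_focal_length(intr2),
               2 * effective_focal_length(intr))
})

test_that("intrinsics validation rejects bad values and warns on aspect", {
  expect_error(camera_intrinsics(-1, 17.3, 9.7, 100, 100))
  expect_error(camera_intrinsics(14, 0, 9.7, 100, 100))
  # non-square pixels: f_pix from width and height disagree
  expect_warning(camera_intrinsics(14, 17.3, 9.7, 4608, 2000), "aspect")
})

test_that("world_to_camera matches hand geometry and is rigid", {
  h <- 5
  p_on_axis <- camera_pose(h, 90, 0, 0)
  expect_equal(world_to_camera(c(0, 7, h), p_on_axis)[1, ],
               c(0, 0, 7), tolerance = 1e-12)
  p_nadir <- camera_pose(h, 0)
  expect_equal(world_to_camera(c(0, 0, 0), p_nadir)[1, ],
               c(0, 0, h), tolerance = 1e-12)
  # rigidity: pairwise distances preserved for arbitrary poses
  set.seed(11)
  for (i in 1:20) {
    pose <- camera_pose(runif(1, 1, 50), runif(1, 0, 179),
                        runif(1, -179, 180), runif(1, 0, 360),
                        runif(1, -10, 10), runif(1, -10, 10))
    p <- matrix(rnorm(9, sd = 20), 3, 3)
    q <- world_to_camera(p, pose)
    expect_equal(as.numeric(dist(q)), as.numeric(dist(p)), tolerance = 1e-9)
    # handedness: determinant of the rotation is +1
    expect_equal(det(pose_rotation(pose)), 1, tolerance = 1e-12)
  }
})

test_that("projection maps the on-axis point to the image centre", {
  intr <- default_intrinsics()
  pose <- camera_pose(5, 90, 0, 0)
  pr <- project(c(0, 30, 5), intr, pose)
  expect_equal(pr$uv[1, ], c(u_px = 2304, v_px = 1296), tolerance = 1e-9)
  expect_true(pr$visible)
})

test_that("rectilinear projection preserves collinearity without distortion", {
  intr <- default_intrinsics()
  pose <- camera_pose(10, 70, 2, 15)
  set.seed(21)
  for (i in 1:25) {
    a <- c(rnorm(2, sd = 10), runif(1, 0, 3))
    b <- a + c(rnorm(2), runif(1))
    mid_t <- runif(1)
    pts <- rbind(a, a + mid_t * (b - a), b)
    pts[, 2] <- pts[, 2] + 40            # keep well in front of the camera
    uv <- project(pts, intr, pose)$uv
    # area of the triangle spanned by the three projections ~ 0
    area <- abs((uv[2, 1] - uv[1, 1]) * (uv[3, 2] - uv[1, 2]) -
                  (uv[3, 1] - uv[1, 1]) * (uv[2, 2] - uv[1, 2])) / 2
    expect_lt(area / max(dist(uv))^2, 1e-9)
  }
})

test_that("points behind a rectilinear camera get sentinel, not mirror", {
  intr <- default_intrinsics()
  pose <- camera_pose(5, 90, 0, 0)           # looking along +y
  pr <- project(rbind(c(0, -10, 5), c(0, 10, 5)), intr, pose)
  expect_true(all(is.na(pr$uv[1, ])))
  expect_false(pr$visible[1])
  expect_true(pr$visible[2])
})

test_that("cylindrical and rectilinear projections agree near the axis", {
  pose <- camera_pose(16.1, 90, 0, 0)
  intr_r <- default_intrinsics()
  intr_c <- camera_intrinsics(14, 17.3, 9.7, 4608, 2592,
                              projection = "cylindrical")
  for (ang_deg in c(0.1, 0.3, 0.5)) {
    ang <- ang_deg * pi / 180
    p <- c(100 * sin(ang), 100 * cos(ang), 16.1)
    du <- abs(project(p, intr_c, pose)$uv[1] - project(p, intr_r, pose)$uv[1])
    expect_lt(du, 0.01)
  }
})

test_that("radial distortion: identity, fixed point, numeric inverse", {
  expect_equal(apply_distortion(c(0.3, -0.2), c(0, 0, 0)),
               matrix(c(0.3, -0.2), 1))
  for (k1 in c(-0.2, -0.05, 0.1, 0.2)) {
    k <- c(k1, 0.02, -0.005)
    expect_equal(apply_distortion(c(0, 0), k), matrix(0, 1, 2))
    set.seed(31)
    ab <- matrix(runif(100, -1, 1) / sqrt(2), 50, 2)  # r <= 1
    back <- invert_distortion(apply_distortion(ab, k), k)
    expect_lt(max(abs(back - ab)), 1e-8)
  }
})

test_that("backprojection recovers the closed-form centre ground distance", {
  intr <- default_intrinsics()
  pose <- camera_pose(16.1, 85.3, 0.3)
  ctr <- c(intr$image_width_px / 2, intr$image_height_px / 2)
  g <- backproject_to_plane(ctr, intr, pose)
  expect_equal(sqrt(sum(g[1, 1:2]^2)),
               center_ground_distance(16.1, 85.3), tolerance = 1e-9)
  pr <- project(g, intr, pose)
  expect_lt(max(abs(pr$uv - matrix(ctr, 1))), 1e-6)
})

test_that("horizontal ray never meets the ground", {
  intr <- default_intrinsics()
  pose <- camera_pose(16.1, 90, 0, 0)
  ctr <- c(intr$image_width_px / 2, intr$image_height_px / 2)
  expect_error(backproject_to_plane(ctr, intr, pose), "no ground")
  # pixels above the horizon likewise
  expect_error(backproject_to_plane(c(2304, 100), intr,
                                    camera_pose(16.1, 85.3)), "no ground")
})

test_that("project after backproject is the identity on ground pixels", {
  pose <- camera_pose(16.1, 85.3, 0.3, 12)
  for (proj in c("rectilinear", "cylindrical", "equirectangular")) {
    for (k in list(c(0, 0, 0), c(-0.08, 0.01, 0))) {
      intr <- camera_intrinsics(14, 17.3, 9.7, 4608, 2592,
                                projection = proj, distortion = k)
      set.seed(41)
      uv <- cbind(runif(1000, 50, 4558), runif(1000, 1500, 2550))
      g <- backproject_to_plane(uv, intr, pose, allow_miss = TRUE)
      ok <- is.finite(g[, 1])
      expect_gt(mean(ok), 0.95)
      uv2 <- project(g[ok, , drop = FALSE], intr, pose)$uv
      expect_lt(max(abs(uv2 - uv[ok, , drop = FALSE])), 1e-6)
    }
  }
})

test_that("foot-constrained head backprojection inverts the generator", {
  intr <- default_intrinsics()
  pose <- default_pose()
  set.seed(51)
  r <- sqrt(runif(50, 50^2, 150^2))
  az <- runif(50, -0.4, 0.4)
  fw <- cbind(r * sin(az), r * cos(az), 0)
  hw <- cbind(fw[, 1:2], 0.75)
  foot_uv <- project(fw, intr, pose)$uv
  head_uv <- project(hw, intr, pose)$uv
  foot_b <- backproject_to_plane(foot_uv, intr, pose)
  head_b <- backproject_with_foot_constraint(head_uv, foot_b, intr, pose)
  expect_lt(max(abs(head_b[, 3] - 0.75)), 1e-6)
  expect_lt(max(abs(head_b[, 1:2] - fw[, 1:2])), 1e-6)
  # head clicked on the foot: zero height
  hb0 <- backproject_with_foot_constraint(foot_uv[1, ], foot_b[1, , drop = FALSE],
                                          intr, pose)
  expect_equal(hb0[1, 3], 0, tolerance = 1e-9)
})

test_that("horizon dip follows the spherical closed form", {
  hm <- horizon_model()
  R <- 6371000
  for (h in c(0.5, 2, 16.1, 100, 1000)) {
    dip <- horizon_dip(h, hm)
    expect_equal(dip, acos(R / (R + h)) * 180 / pi, tolerance = 1e-12)
    # small-height approximation within 1%
    expect_equal(dip, sqrt(2 * h / R) * 180 / pi, tolerance = 0.01)
  }
  expect_equal(horizon_dip(16.1), 0.128809, tolerance = 1e-4)
  # h -> 0: dip vanishes
  expect_lt(horizon_dip(1e-9), 1e-5)
})

test_that("horizon trace: row position, roll slope, out-of-frame empty", {
  intr <- default_intrinsics()
  f <- effective_focal_length(intr)
  # zero roll: horizontal line at the row of the dipped horizontal
  pose <- camera_pose(16.1, 85.3, 0)
  hz <- horizon_in_image(intr, pose, n_points = 21)
  expect_gt(nrow(hz), 5)
  v_pred <- intr$image_height_px / 2 +
    f * tan((85.3 + horizon_dip(16.1) - 90) * pi / 180)
  # exact at the image centre; the projected circle bows ~1 px at the edges
  ctr_pt <- hz[which.min(abs(hz[, 1] - intr$image_width_px / 2)), ]
  expect_lt(abs(ctr_pt[2] - v_pred), 0.1)
  expect_lt(diff(range(hz[, 2])), 3)
  # roll tips the trace by ~tan(roll)
  hz5 <- horizon_in_image(intr, camera_pose(16.1, 85.3, 5), n_points = 30)
  slope <- coef(lm(hz5[, 2] ~ hz5[, 1]))[[2]]
  expect_equal(abs(slope), tan(5 * pi / 180), tolerance = 0.02)
  # camera pointing well below the horizon: empty trace, no error
  expect_equal(nrow(horizon_in_image(intr, camera_pose(16.1, 40), n_points = 10)),
               0)
})
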