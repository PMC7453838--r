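# Independent oracles used across tests.

# Standard computer-vision calibration matrix for a rectilinear camera.
k_matrix <- function(intr) {
  f <- effective_focal_length(intr)
  rbind(c(f, 0, intr$image_width_px / 2),
        c(0, f, intr$image_height_px / 2),
        c(0, 0, 1))
}

cam_center <- function(pose) c(pose$pos_x_m, pose$pos_y_m, pose$elevation_m)

# Fundamental matrix assembled from the known camera poses (epipolar-geometry
# textbook construction), independent of the package's geometric epipolar
# line. Returns distances from points_b to the lines F %*% points_a.
fmatrix_distances <- function(cam_a, cam_b, points_a, points_b) {
  Ra <- pose_rotation(cam_a$pose); Rb <- pose_rotation(cam_b$pose)
  ca <- cam_center(cam_a$pose); cb <- cam_center(cam_b$pose)
  Rrel <- Rb %*% t(Ra)
  trel <- as.numeric(Rb %*% (ca - cb))
  tx <- rbind(c(0, -trel[3], trel[2]),
              c(trel[3], 0, -trel[1]),
              c(-trel[2], trel[1], 0))
  Fm <- t(solve(k_matrix(cam_b$intrinsics))) %*% tx %*% Rrel %*%
    solve(k_matrix(cam_a$intrinsics))
  vapply(seq_len(nrow(points_a)), function(i) {
    l <- Fm %*% c(points_a[i, ], 1)
    abs(sum(l * c(points_b[i, ], 1))) / sqrt(sum(l[1:2]^2))
  }, numeric(1))
}

# True scale-free relative parameters (az, incl, dtilt, droll, dheading)
# between two known cameras, in the package's parameterisation.
true_rel_params <- function(cam_a, cam_b) {
  off <- cam_center(cam_b$pose) - cam_center(cam_a$pose)
  c(az = (atan2(off[1], off[2]) * 180 / pi) %% 360,
    incl = asin(off[3] / sqrt(sum(off^2))) * 180 / pi,
    dtilt = cam_b$pose$tilt_deg - cam_a$pose$tilt_deg,
    droll = cam_b$pose$roll_deg - cam_a$pose$roll_deg,
    dheading = cam_b$pose$heading_deg - cam_a$pose$heading_deg)
}

# Distance of the ground point seen at the image centre, closed form.
center_ground_distance <- function(elevation_m, tilt_deg) {
  elevation_m * tan(tilt_deg * pi / 180)
}
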