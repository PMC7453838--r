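#' Camera intrinsic parameters
#'
#' Bundle of the hardware properties of a camera/lens combination: focal
#' length, physical sensor dimensions, image dimensions in pixels, the
#' projection model of the lens, and radial distortion coefficients.
#'
#' The effective focal length in pixels is
#' `f_pix = focal_length_mm * image_width_px / sensor_width_mm`; the
#' principal point is fixed at the image centre `(w/2, h/2)`. Pixels are
#' assumed square: the focal length computed from the sensor/image heights
#' must agree with `f_pix` within `aspect_tol` (relative), otherwise a
#' warning is emitted.
#'
#' @param focal_length_mm focal length of the lens in mm (> 0).
#' @param sensor_width_mm,sensor_height_mm physical sensor size in mm (> 0).
#' @param image_width_px,image_height_px image size in pixels (> 0).
#' @param projection one of `"rectilinear"` (pinhole), `"cylindrical"`,
#'   `"equirectangular"` (panoramic models).
#' @param distortion numeric triple `(k1, k2, k3)` of radial distortion
#'   coefficients; `c(0, 0, 0)` means an ideal lens.
#' @param aspect_tol relative tolerance for the square-pixel check.
#' @return An object of class `"camera_intrinsics"`.
#' @examples
#' intr <- camera_intrinsics(14, 17.3, 9.7, 4608, 2592)
#' effective_focal_length(intr)
#' @export
camera_intrinsics <- function(focal_length_mm,
                              sensor_width_mm, sensor_height_mm,
                              image_width_px, image_height_px,
                              projection = c("rectilinear", "cylindrical",
                                             "equirectangular"),
                              distortion = c(0, 0, 0),
                              aspect_tol = 0.01) {
  projection <- match.arg(projection)
  stopifnot(is.numeric(focal_length_mm), focal_length_mm > 0,
            is.numeric(sensor_width_mm), sensor_width_mm > 0,
            is.numeric(sensor_height_mm), sensor_height_mm > 0,
            is.numeric(image_width_px), image_width_px > 0,
            is.numeric(image_height_px), image_height_px > 0,
            is.numeric(distortion), length(distortion) == 3,
            all(is.finite(distortion)))
  f_w <- focal_length_mm * image_width_px / sensor_width_mm
  f_h <- focal_length_mm * image_height_px / sensor_height_mm
  if (abs(f_w - f_h) / f_w > aspect_tol)
    warning(sprintf(paste0("sensor and image aspect ratios disagree: ",
                           "f_pix from width = %.2f px, from height = %.2f px ",
                           "(non-square pixels?)"), f_w, f_h))
  structure(list(focal_length_mm = as.numeric(focal_length_mm),
                 sensor_width_mm = as.numeric(sensor_width_mm),
                 sensor_height_mm = as.numeric(sensor_height_mm),
                 image_width_px = as.numeric(image_width_px),
                 image_height_px = as.numeric(image_height_px),
                 projection = projection,
                 distortion = as.numeric(distortion)),
            class = "camera_intrinsics")
}

#' Effective focal length in pixels
#'
#' Rescales the focal length from mm on the sensor to pixels in the image:
#' `f_pix = f * w_image / w_sensor`.
#'
#' @param intr a [camera_intrinsics()] object.
#' @return Focal length in pixel units.
#' @export
effective_focal_length <- function(intr) {
  stopifnot(inherits(intr, "camera_intrinsics"))
  intr$focal_length_mm * intr$image_width_px / intr$sensor_width_mm
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("Camera intrinsics (%s projection)\n", x$projection))
  cat(sprintf("  focal length : %.4g mm (%.2f px effective)\n",
              x$focal_length_mm, effective_focal_length(x)))
  cat(sprintf("  sensor       : %.4g x %.4g mm\n",
              x$sensor_width_mm, x$sensor_height_mm))
  cat(sprintf("  image        : %d x %d px\n",
              as.integer(x$image_width_px), as.integer(x$image_height_px)))
  cat(sprintf("  distortion   : k = (%g, %g, %g)\n",
              x$distortion[1], x$distortion[2], x$distortion[3]))
  invisible(x)
}

#' Camera pose (extrinsic parameters)
#'
#' Placement of the camera relative to the world frame. The world frame has
#' z pointing up with z = 0 the reference ground plane; the camera sits at
#' `(pos_x_m, pos_y_m, elevation_m)`.
#'
#' Angles are in degrees at the interface:
#' * `tilt_deg` — angle between the vertical and the optical axis; 0 looks
#'   straight down (nadir), 90 is horizontal. Range `[0, 180)`.
#' * `roll_deg` — rotation about the optical axis, 0 when the lower sensor
#'   edge is horizontal. Range `(-180, 180]`.
#' * `heading_deg` — azimuth of the viewing direction, measured clockwise
#'   from the world +y axis (map convention). Range `[0, 360)`.
#'
#' @param elevation_m camera height above the z = 0 plane in m (> 0 required
#'   for ground backprojection).
#' @param tilt_deg,roll_deg,heading_deg orientation angles in degrees.
#' @param pos_x_m,pos_y_m camera position in the ground plane, m.
#' @return An object of class `"camera_pose"`.
#' @export
camera_pose <- function(elevation_m, tilt_deg, roll_deg = 0,
                        heading_deg = 0, pos_x_m = 0, pos_y_m = 0) {
  stopifnot(is.numeric(elevation_m), is.finite(elevation_m),
            is.numeric(tilt_deg), is.finite(tilt_deg),
            is.numeric(roll_deg), is.finite(roll_deg),
            is.numeric(heading_deg), is.finite(heading_deg),
            is.finite(pos_x_m), is.finite(pos_y_m))
  if (tilt_deg < 0 || tilt_deg >= 180)
    stop("tilt_deg must lie in [0, 180)")
  if (roll_deg <= -180 || roll_deg > 180)
    stop("roll_deg must lie in (-180, 180]")
  heading_deg <- heading_deg %% 360
  structure(list(elevation_m = as.numeric(elevation_m),
                 tilt_deg = as.numeric(tilt_deg),
                 roll_deg = as.numeric(roll_deg),
                 heading_deg = as.numeric(heading_deg),
                 pos_x_m = as.numeric(pos_x_m),
                 pos_y_m = as.numeric(pos_y_m)),
            class = "camera_pose")
}

#' @export
print.camera_pose <- function(x, ...) {
  cat("Camera pose\n")
  cat(sprintf("  elevation : %.3f m at (%.2f, %.2f) m\n",
              x$elevation_m, x$pos_x_m, x$pos_y_m))
  cat(sprintf("  tilt %.3f deg, roll %.3f deg, heading %.3f deg\n",
              x$tilt_deg, x$roll_deg, x$heading_deg))
  invisible(x)
}

#' Bundle intrinsics and pose into a camera
#'
#' @param intrinsics a [camera_intrinsics()] object.
#' @param pose a [camera_pose()] object.
#' @return An object of class `"camera"` with elements `intrinsics`, `pose`.
#' @export
camera <- function(intrinsics, pose) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"),
            inherits(pose, "camera_pose"))
  structure(list(intrinsics = intrinsics, pose = pose), class = "camera")
}

#' @export
print.camera <- function(x, ...) {
  print(x$intrinsics)
  print(x$pose)
  invisible(x)
}

#' Read / write a camera configuration file
#'
#' The configuration is a YAML (or JSON, chosen by extension) mapping with
#' keys `focal_length_mm`, `sensor_size_mm` (`[w, h]`), `image_size_px`
#' (`[w, h]`), `projection`, `distortion` (`[k1, k2, k3]`) and a `pose`
#' mapping with `elevation_m`, `tilt_deg`, `roll_deg`, `heading_deg`,
#' `pos_x_m`, `pos_y_m`. Read and write round-trip exactly.
#'
#' @param path file path; `.json` is parsed as JSON, anything else as YAML.
#' @return `read_camera` returns a [camera()] object.
#' @export
read_camera <- function(path) {
  if (!file.exists(path)) stop("camera config not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  need <- c("focal_length_mm", "sensor_size_mm", "image_size_px",
            "projection", "pose")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("camera config missing keys: ", paste(miss, collapse = ", "))
  k <- if (is.null(cfg$distortion)) c(0, 0, 0) else as.numeric(cfg$distortion)
  intr <- camera_intrinsics(cfg$focal_length_mm,
                            cfg$sensor_size_mm[[1]], cfg$sensor_size_mm[[2]],
                            cfg$image_size_px[[1]], cfg$image_size_px[[2]],
                            projection = cfg$projection, distortion = k)
  p <- cfg$pose
  pose <- camera_pose(p$elevation_m, p$tilt_deg,
                      roll_deg = if (is.null(p$roll_deg)) 0 else p$roll_deg,
                      heading_deg = if (is.null(p$heading_deg)) 0 else p$heading_deg,
                      pos_x_m = if (is.null(p$pos_x_m)) 0 else p$pos_x_m,
                      pos_y_m = if (is.null(p$pos_y_m)) 0 else p$pos_y_m)
  camera(intr, pose)
}

#' @param cam a [camera()] object.
#' @rdname read_camera
#' @export
write_camera <- function(cam, path) {
  stopifnot(inherits(cam, "camera"))
  intr <- cam$intrinsics; pose <- cam$pose
  cfg <- list(focal_length_mm = intr$focal_length_mm,
              sensor_size_mm = c(intr$sensor_width_mm, intr$sensor_height_mm),
              image_size_px = c(intr$image_width_px, intr$image_height_px),
              projection = intr$projection,
              distortion = intr$distortion,
              pose = list(elevation_m = pose$elevation_m,
                          tilt_deg = pose$tilt_deg,
                          roll_deg = pose$roll_deg,
                          heading_deg = pose$heading_deg,
                          pos_x_m = pose$pos_x_m,
                          pos_y_m = pose$pos_y_m))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  else
    yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
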