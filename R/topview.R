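#' Project an image to a metric top view
#'
#' Resamples an oblique image onto a regular grid on the ground plane
#' (z = 0), producing a bird's-eye view in metres. The warp is inverse:
#' each output grid cell centre is projected into the source image with
#' [project()] and samples the nearest source pixel. Cells whose ground
#' point is not visible (outside the frame, or above the horizon so that it
#' never projects) become no-data, encoded in the alpha channel.
#'
#' @param image_raster a numeric array `h x w` (grey), `h x w x 3` (RGB) or
#'   `h x w x 4` (RGBA) with values in `[0, 1]`, as returned by
#'   [png::readPNG()]; array rows run top to bottom like image v.
#' @param intr,pose the camera that took the image.
#' @param extent_m numeric `c(xmin, xmax, ymin, ymax)` of the ground region
#'   to render, metres in world coordinates.
#' @param resolution_m_per_px size of one output pixel in metres (> 0).
#' @return An array `ny x nx x 4` (RGBA); alpha 0 marks no-data. Attributes
#'   `extent_m` and `resolution_m_per_px` record the georeferencing; the
#'   first row of the array is the row of maximal y (north up).
#' @export
topview_map <- function(image_raster, intr, pose, extent_m,
                        resolution_m_per_px) {
  if (!is.numeric(resolution_m_per_px) || resolution_m_per_px <= 0)
    stop("resolution_m_per_px must be a positive number")
  stopifnot(length(extent_m) == 4, extent_m[2] > extent_m[1],
            extent_m[4] > extent_m[3])
  dm <- dim(image_raster)
  if (length(dm) == 2) {
    image_raster <- array(rep(image_raster, 3), dim = c(dm, 3))
    dm <- dim(image_raster)
  }
  src_h <- dm[1]; src_w <- dm[2]; src_ch <- dm[3]
  nx <- max(1, round((extent_m[2] - extent_m[1]) / resolution_m_per_px))
  ny <- max(1, round((extent_m[4] - extent_m[3]) / resolution_m_per_px))
  xs <- extent_m[1] + (seq_len(nx) - 0.5) * resolution_m_per_px
  ys <- extent_m[4] - (seq_len(ny) - 0.5) * resolution_m_per_px  # north up
  grid <- cbind(rep(xs, each = ny), rep(ys, times = nx), 0)
  pr <- project(grid, intr, pose)
  ## nearest-neighbour source pixel; pixel (i, j) covers [j-1, j] x [i-1, i]
  col <- ceiling(pr$uv[, 1]); row <- ceiling(pr$uv[, 2])
  col[col == 0] <- 1L; row[row == 0] <- 1L
  ok <- pr$visible & !is.na(col) & !is.na(row) &
    col >= 1 & col <= src_w & row >= 1 & row <= src_h
  out <- array(0, dim = c(ny, nx, 4))
  idx_ok <- which(ok)
  lin <- row[idx_ok] + (col[idx_ok] - 1) * src_h
  for (ch in 1:3) {
    src_ch_idx <- min(ch, src_ch)
    plane <- matrix(0, ny, nx)
    plane[idx_ok] <- image_raster[lin + (src_ch_idx - 1) * src_h * src_w]
    out[, , ch] <- plane
  }
  alpha <- matrix(0, ny, nx)
  if (src_ch == 4) {
    alpha[idx_ok] <- image_raster[lin + 3 * src_h * src_w]
  } else alpha[idx_ok] <- 1
  out[, , 4] <- alpha
  attr(out, "extent_m") <- extent_m
  attr(out, "resolution_m_per_px") <- resolution_m_per_px
  out
}

#' Read or write a raster image
#'
#' Thin wrappers over the png (and, when installed, tiff) packages used by
#' the top-view pipeline; no-data travels in the alpha channel.
#'
#' @param path file path; format chosen by extension (`.png`, `.tif(f)`).
#' @return `read_raster` returns a numeric array with values in `[0, 1]`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster not found: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the tiff package is required to read TIFF files")
    tiff::readTIFF(path)
  } else png::readPNG(path)
}

#' @param raster numeric array as produced by [topview_map()].
#' @rdname read_raster
#' @export
write_raster <- function(raster, path) {
  attr(raster, "extent_m") <- NULL
  attr(raster, "resolution_m_per_px") <- NULL
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the tiff package is required to write TIFF files")
    tiff::writeTIFF(raster, path)
  } else png::writePNG(raster, path)
  invisible(path)
}
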