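## CSV dialects (one per entity, UTF-8, header required):
##   clicks:      type {foot,head,horizon}, pair_id, u_px, v_px
##   landmarks:   u_px, v_px, lat, lon        (or u_px, v_px, x_m, y_m)
##   corr:        pair_id, camera {a,b}, u_px, v_px

.read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        comment.char = "#", fileEncoding = "UTF-8")
  if (nrow(df) == 0) stop("empty table: ", path)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(path, ": missing required column(s): ", paste(miss, collapse = ", "))
  df
}

.check_numeric <- function(df, cols, path) {
  for (cl in cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (any(is.na(v)))
      stop(path, ": non-numeric or missing values in column '", cl,
           "' (data row", if (length(bad)) paste0(" ", bad[1]) else "", ")")
    df[[cl]] <- v
  }
  df
}

#' Read and write click tables
#'
#' Clicks are stored one per row with columns `type` (`foot`, `head` or
#' `horizon`), `pair_id` (shared by the foot and head of one object; empty
#' for horizon rows), `u_px`, `v_px`.
#'
#' @param path CSV file path.
#' @param noise_px click-noise scale attached to the returned set.
#' @return `read_clicks` returns a [click_set()].
#' @export
read_clicks <- function(path, noise_px = 1) {
  df <- .read_csv_checked(path, c("type", "pair_id", "u_px", "v_px"))
  df <- .check_numeric(df, c("u_px", "v_px"), path)
  bad <- !df$type %in% c("foot", "head", "horizon")
  if (any(bad))
    stop(path, ": unknown click type '", df$type[which(bad)[1]],
         "' (data row ", which(bad)[1], ")")
  foot <- df[df$type == "foot", ]
  head_ <- df[df$type == "head", ]
  if (nrow(foot) == 0 || nrow(head_) == 0)
    stop(path, ": need at least one foot and one head click")
  ids <- sort(unique(foot$pair_id))
  if (!setequal(ids, unique(head_$pair_id)) ||
      nrow(foot) != length(ids) || nrow(head_) != length(ids))
    stop(path, ": foot/head pair_ids do not match one-to-one")
  foot <- foot[match(ids, foot$pair_id), ]
  head_ <- head_[match(ids, head_$pair_id), ]
  hor <- df[df$type == "horizon", ]
  click_set(as.matrix(foot[, c("u_px", "v_px")]),
            as.matrix(head_[, c("u_px", "v_px")]),
            horizon = if (nrow(hor)) as.matrix(hor[, c("u_px", "v_px")]),
            noise_px = noise_px)
}

#' @param clicks a [click_set()].
#' @rdname read_clicks
#' @export
write_clicks <- function(clicks, path) {
  stopifnot(inherits(clicks, "click_set"))
  n <- nrow(clicks$foot)
  df <- rbind(data.frame(type = "foot", pair_id = seq_len(n),
                         u_px = clicks$foot[, 1], v_px = clicks$foot[, 2]),
              data.frame(type = "head", pair_id = seq_len(n),
                         u_px = clicks$head[, 1], v_px = clicks$head[, 2]))
  if (!is.null(clicks$horizon))
    df <- rbind(df, data.frame(type = "horizon",
                               pair_id = NA_integer_,
                               u_px = clicks$horizon[, 1],
                               v_px = clicks$horizon[, 2]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write landmark tables
#'
#' Columns `u_px`, `v_px` plus either `lat`, `lon` (converted to a local
#' tangent frame about their centroid) or `x_m`, `y_m` (used as-is with
#' `local = TRUE`).
#'
#' @param path CSV file path.
#' @param local targets are already metric (`x_m`, `y_m` columns).
#' @return `read_landmarks` returns a [landmark_set()]; when converted
#'   from lat/lon the reference origin is stored in attribute `ref_latlon`.
#' @export
read_landmarks <- function(path, local = FALSE) {
  if (local) {
    df <- .read_csv_checked(path, c("u_px", "v_px", "x_m", "y_m"))
    df <- .check_numeric(df, c("u_px", "v_px", "x_m", "y_m"), path)
    lm <- landmark_set(as.matrix(df[, c("u_px", "v_px")]),
                       as.matrix(df[, c("x_m", "y_m")]))
  } else {
    df <- .read_csv_checked(path, c("u_px", "v_px", "lat", "lon"))
    df <- .check_numeric(df, c("u_px", "v_px", "lat", "lon"), path)
    ref <- c(mean(df$lat), mean(df$lon))
    xy <- latlon_to_local(df$lat, df$lon, ref[1], ref[2])
    lm <- landmark_set(as.matrix(df[, c("u_px", "v_px")]), xy)
    attr(lm, "ref_latlon") <- ref
  }
  lm
}

#' @param lm a [landmark_set()].
#' @rdname read_landmarks
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  df <- data.frame(u_px = lm$image_points[, 1], v_px = lm$image_points[, 2],
                   x_m = lm$target_points[, 1], y_m = lm$target_points[, 2])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write stereo correspondence tables
#'
#' Columns `pair_id`, `camera` (`a` or `b`), `u_px`, `v_px`; each pair_id
#' must appear exactly once per camera. The scale constraint is supplied
#' separately (function argument or CLI flag).
#'
#' @param path CSV file path.
#' @param baseline_m,known_size scale constraint, see
#'   [correspondence_set()].
#' @return `read_corr` returns a [correspondence_set()].
#' @export
read_corr <- function(path, baseline_m = NULL, known_size = NULL) {
  df <- .read_csv_checked(path, c("pair_id", "camera", "u_px", "v_px"))
  df <- .check_numeric(df, c("u_px", "v_px"), path)
  bad <- !df$camera %in% c("a", "b")
  if (any(bad))
    stop(path, ": camera column must be 'a' or 'b' (data row ",
         which(bad)[1], ")")
  a <- df[df$camera == "a", ]; b <- df[df$camera == "b", ]
  ids <- sort(unique(a$pair_id))
  if (!setequal(ids, unique(b$pair_id)) ||
      nrow(a) != length(ids) || nrow(b) != length(ids))
    stop(path, ": pair_ids do not match one-to-one between cameras")
  a <- a[match(ids, a$pair_id), ]; b <- b[match(ids, b$pair_id), ]
  correspondence_set(as.matrix(a[, c("u_px", "v_px")]),
                     as.matrix(b[, c("u_px", "v_px")]),
                     baseline_m = baseline_m, known_size = known_size)
}

#' @param corr a [correspondence_set()].
#' @rdname read_corr
#' @export
write_corr <- function(corr, path) {
  stopifnot(inherits(corr, "correspondence_set"))
  n <- nrow(corr$points_a)
  df <- rbind(data.frame(pair_id = seq_len(n), camera = "a",
                         u_px = corr$points_a[, 1], v_px = corr$points_a[, 2]),
              data.frame(pair_id = seq_len(n), camera = "b",
                         u_px = corr$points_b[, 1], v_px = corr$points_b[, 2]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to replay a run exactly: the command and
#' arguments, MD5 hashes of the input files, the seed, the package version
#' and a timestamp. Deterministic or seeded commands re-run from an
#' identical manifest reproduce identical outputs.
#'
#' @param dir output directory (created if needed).
#' @param command subcommand name.
#' @param args character vector of arguments as received.
#' @param inputs named character vector of input file paths to hash.
#' @param seed the seed in effect.
#' @return Path of the written `run_manifest.json`, invisibly.
#' @export
write_manifest <- function(dir, command, args = character(),
                           inputs = character(), seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hashes <- if (length(inputs))
    as.list(tools::md5sum(unlist(inputs))) else list()
  manifest <- list(command = command,
                   args = as.list(args),
                   input_md5 = hashes,
                   seed = seed,
                   package = "camfit",
                   version = as.character(utils::packageVersion("camfit")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
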