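#' Read and write the package's delimited-text formats
#'
#' Two-column time-series CSVs (`time_s` + a value column), signal schedules
#' (`potential_V`, `duration_s`; CSV or YAML), cytometry event tables
#' (`fsc`, `ssc`, `green`) and multi-page 16-bit grayscale TIFF stacks.
#' CSVs are comma-separated, '.'-decimal, UTF-8, header mandatory; values
#' round-trip to at least 12 significant digits and TIFF pixel data
#' round-trips bit-exactly. Malformed inputs (ragged rows, missing headers,
#' non-monotone time columns) are rejected with the offending row number.
#'
#' @param x object to write
#' @param path file path
#' @name electro_io
NULL

.write_csv <- function(df, path) {
  utils::write.table(format(df, digits = 15, scientific = NA, trim = TRUE),
                     path, sep = ",", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

.read_csv_strict <- function(path, required_cols) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1L) stop_invalid("%s: empty file", path)
  nfield <- lengths(strsplit(lines, ",", fixed = TRUE))
  bad <- which(nfield != nfield[1])
  if (length(bad))
    stop_invalid("%s: ragged row at line %d", path, bad[1])
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop_invalid("%s: missing column(s) %s", path,
                 paste(missing, collapse = ", "))
  df
}

.check_time_monotone <- function(df, path) {
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad))
    stop_invalid("%s: time column not strictly increasing at data row %d",
                 path, bad[1] + 1L)
  df
}

#' @rdname electro_io
#' @export
write_current_trace <- function(x, path) {
  .write_csv(data.frame(time_s = x$time_s, value = x$current_A), path)
}

#' @rdname electro_io
#' @export
read_current_trace <- function(path) {
  df <- .check_time_monotone(.read_csv_strict(path, c("time_s", "value")),
                             path)
  current_trace(df$time_s, df$value)
}

#' @rdname electro_io
#' @export
write_expression_trace <- function(x, path) {
  .write_csv(data.frame(time_s = x$time_s, fluor_au = x$fluor_au), path)
}

#' @rdname electro_io
#' @export
read_expression_trace <- function(path) {
  df <- .check_time_monotone(
    .read_csv_strict(path, c("time_s", "fluor_au")), path)
  expression_trace(df$time_s, df$fluor_au)
}

#' @rdname electro_io
#' @export
write_signal_schedule <- function(x, path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(list(segments = lapply(seq_len(nrow(x)), function(i)
      list(potential_V = x$potential_V[i], duration_s = x$duration_s[i]))),
      path)
    invisible(path)
  } else {
    .write_csv(as.data.frame(x), path)
  }
}

#' @rdname electro_io
#' @export
read_signal_schedule <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    segs <- y$segments
    signal_schedule(
      vapply(segs, function(s)
        if (is.null(s$potential_V)) NA_real_ else as.numeric(s$potential_V),
        numeric(1)),
      vapply(segs, function(s) as.numeric(s$duration_s), numeric(1)))
  } else {
    df <- .read_csv_strict(path, c("potential_V", "duration_s"))
    signal_schedule(df$potential_V, df$duration_s)
  }
}

#' @rdname electro_io
#' @export
write_event_table <- function(x, path) {
  .write_csv(as.data.frame(x)[, c("fsc", "ssc", "green")], path)
}

#' @rdname electro_io
#' @export
read_event_table <- function(path) {
  df <- .read_csv_strict(path, c("fsc", "ssc", "green"))
  event_table(df$fsc, df$ssc, df$green)
}

#' @rdname electro_io
#' @param fps,pixel_size acquisition metadata for the returned
#'   [video_stack]; when `NULL`, `read_video_stack` looks for a YAML sidecar
#'   `<path>.yaml` with `fps`/`pixel_size` keys
#' @export
write_video_stack <- function(x, path) {
  stopifnot(inherits(x, "video_stack"))
  pages <- lapply(x$frames, function(f) f / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(list(fps = x$fps, pixel_size = x$pixel_size),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname electro_io
#' @export
read_video_stack <- function(path, fps = NULL, pixel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    m <- round(p * 65535)
    matrix(as.integer(m), nrow(m), ncol(m))
  })
  if (is.null(fps) || is.null(pixel_size)) {
    sidecar <- paste0(path, ".yaml")
    if (file.exists(sidecar)) {
      meta <- yaml::read_yaml(sidecar)
      if (is.null(fps)) fps <- meta$fps
      if (is.null(pixel_size)) pixel_size <- meta$pixel_size
    }
  }
  if (is.null(fps) || is.null(pixel_size))
    stop_invalid("fps and pixel_size are required (argument or YAML sidecar)")
  video_stack(frames, fps, pixel_size)
}

#' @rdname electro_io
#' @export
write_trajectories <- function(x, path) {
  rows <- do.call(rbind, lapply(x, function(tr) {
    d <- tr$detections
    data.frame(track_id = tr$id, frame = d$frame, x_px = d$x, y_px = d$y,
               area = d$area, intensity = d$mean_intensity)
  }))
  if (is.null(rows))
    rows <- data.frame(track_id = integer(0), frame = integer(0),
                       x_px = numeric(0), y_px = numeric(0),
                       area = numeric(0), intensity = numeric(0))
  .write_csv(rows, path)
}

#' @rdname electro_io
#' @param n_frames,fps,pixel_size metadata restored onto the trajectory set
#' @export
read_trajectories <- function(path, n_frames = NULL, fps = NULL,
                              pixel_size = NULL) {
  df <- .read_csv_strict(path, c("track_id", "frame", "x_px", "y_px",
                                 "area", "intensity"))
  out <- lapply(unique(df$track_id), function(id) {
    d <- df[df$track_id == id, ]
    structure(list(id = id,
                   detections = data.frame(frame = d$frame, x = d$x_px,
                                           y = d$y_px, area = d$area,
                                           mean_intensity = d$intensity)),
              class = "trajectory")
  })
  structure(out, class = "trajectory_set",
            n_frames = if (is.null(n_frames) && nrow(df)) max(df$frame)
                       else n_frames,
            fps = fps, pixel_size = pixel_size)
}
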