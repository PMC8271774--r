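#' Read and write landmark streams
#'
#' The CSV dialect has a header `frame,x0,y0,...,x67,y67` with 0-based frame
#' numbers; recording metadata (`fps`, `subject`, `emotion`, `authenticity`)
#' lives in a sidecar JSON file. The single-file JSON dialect bundles both.
#'
#' @param stream A `landmark_stream`.
#' @param path Output/input file path.
#' @param meta_path Path of the sidecar JSON (defaults to `path` with the
#'   extension replaced by `.json` for writing; optional for reading if `fps`
#'   is supplied).
#' @param fps Sampling rate override when no sidecar is available.
#' @return `read_*` return a `landmark_stream`; `write_*` return `path`
#'   invisibly.
#' @name landmark_io
NULL

#' @rdname landmark_io
#' @export
write_landmark_csv <- function(stream, path, meta_path = NULL) {
  stopifnot(inherits(stream, "landmark_stream"))
  df <- data.frame(frame = stream$frame_index, stream$coords,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (is.null(meta_path)) meta_path <- sub("\\.[^.]+$", ".json", path)
  meta <- c(list(fps = stream$fps), stream$meta)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname landmark_io
#' @export
read_landmark_csv <- function(path, meta_path = NULL, fps = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df)[1], "frame")) {
    stop("expected first column 'frame' in ", path, call. = FALSE)
  }
  meta <- list(subject = NA_character_, emotion = NA_character_,
               authenticity = NA_character_)
  if (is.null(meta_path)) {
    candidate <- sub("\\.[^.]+$", ".json", path)
    if (file.exists(candidate)) meta_path <- candidate
  }
  if (!is.null(meta_path)) {
    m <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (is.null(fps)) fps <- m$fps
    for (f in names(meta)) if (!is.null(m[[f]])) meta[[f]] <- m[[f]]
  }
  if (is.null(fps)) stop("fps not given and no sidecar JSON found", call. = FALSE)
  landmark_stream(as.matrix(df[, -1L, drop = FALSE]), fps = fps,
                  subject = meta$subject, emotion = meta$emotion,
                  authenticity = meta$authenticity,
                  frame_index = df$frame)
}

#' @rdname landmark_io
#' @export
write_landmark_json <- function(stream, path) {
  stopifnot(inherits(stream, "landmark_stream"))
  obj <- list(
    fps = stream$fps, subject = stream$meta$subject,
    emotion = stream$meta$emotion, authenticity = stream$meta$authenticity,
    frame = stream$frame_index,
    coords = unname(stream$coords)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname landmark_io
#' @export
read_landmark_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  landmark_stream(obj$coords, fps = obj$fps,
                  subject = obj$subject %||% NA_character_,
                  emotion = obj$emotion %||% NA_character_,
                  authenticity = obj$authenticity %||% NA_character_,
                  frame_index = obj$frame)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an RR-interval series from CSV
#'
#' Accepts a single-column CSV of successive intervals in seconds, or a
#' two-column `(time, interval)` CSV (the time column is ignored; intervals
#' define their own time base).
#'
#' @param path Input CSV path.
#' @param ... Passed to [rr_series()] (e.g. `subject`, `condition`).
#' @return An `rr_series`.
#' @export
read_rr_csv <- function(path, ...) {
  df <- utils::read.csv(path)
  intervals <- if (ncol(df) >= 2L) df[[2L]] else df[[1L]]
  rr_series(intervals, ...)
}

#' Write an RR-interval series to a single-column CSV
#' @param rr An `rr_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rr_csv <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  utils::write.csv(data.frame(interval_s = rr$intervals), path,
                   row.names = FALSE)
  invisible(path)
}
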