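#' The eleven action-unit definitions
#'
#' Each action unit (AU) is operationalised as the centroid of three facial
#' landmarks from the standard 68-point annotation scheme. Landmark indices
#' are 0-based labels, the convention of the 68-point landmark model (the
#' largest index used is 63). Left/right refer to the viewer's left/right of
#' the image; `side` is derived from the `_L`/`_R`/`_M` suffix.
#'
#' @return A tibble with columns `au`, `description`, `landmarks` (list column
#'   of 0-based integer triples) and `side`.
#' @export
#' @examples
#' au_definitions()
au_definitions <- function() {
  defs <- list(
    list("AU4_M",  "Brow depressor",       c(21L, 22L, 27L)),
    list("AU5_L",  "Upper lid raiser",     c(23L, 25L, 44L)),
    list("AU5_R",  "Upper lid raiser",     c(18L, 20L, 37L)),
    list("AU6_L",  "Cheek raiser",         c(15L, 26L, 45L)),
    list("AU6_R",  "Cheek raiser",         c(1L, 17L, 36L)),
    list("AU12_L", "Lip corner puller",    c(14L, 35L, 54L)),
    list("AU12_R", "Lip corner puller",    c(2L, 31L, 48L)),
    list("AU15_L", "Lip corner depressor", c(10L, 11L, 54L)),
    list("AU15_R", "Lip corner depressor", c(5L, 6L, 48L)),
    list("AU23_L", "Lip tightener",        c(52L, 53L, 63L)),
    list("AU23_R", "Lip tightener",        c(49L, 50L, 61L))
  )
  au <- vapply(defs, `[[`, character(1), 1L)
  suffix <- sub(".*_", "", au)
  tibble::tibble(
    au = au,
    description = vapply(defs, `[[`, character(1), 2L),
    landmarks = lapply(defs, `[[`, 3L),
    side = c(L = "left", R = "right", M = "middle")[suffix]
  )
}

#' Valid emotion and authenticity labels
#' @keywords internal
#' @noRd
.emotions <- c("happiness", "contentment", "anger", "sadness")
.authenticities <- c("real", "fake")

#' Centroid of three 2-D points
#'
#' The AU position in a frame: the componentwise arithmetic mean of the three
#' landmark coordinates that define the unit.
#'
#' @param p1,p2,p3 Numeric length-2 vectors `(x, y)`.
#' @return Numeric length-2 vector, the centroid.
#' @export
#' @examples
#' au_centroid(c(0, 0), c(3, 0), c(0, 3))
au_centroid <- function(p1, p2, p3) {
  pts <- rbind(p1, p2, p3)
  if (!is.numeric(pts) || ncol(pts) != 2L || !all(is.finite(pts))) {
    stop("au_centroid() requires three finite (x, y) points", call. = FALSE)
  }
  colMeans(pts)
}

#' Construct a landmark stream
#'
#' A landmark stream is a per-frame sequence of 68 `(x, y)` pixel coordinates
#' at a fixed sampling rate, with recording metadata. Coordinates are raw
#' image-space pixels, y increasing downward.
#'
#' @param coords Numeric matrix with one row per frame and 136 columns in the
#'   order `x0, y0, x1, y1, ..., x67, y67`.
#' @param fps Sampling rate in frames per second (> 0).
#' @param subject Subject identifier.
#' @param emotion One of `"happiness"`, `"contentment"`, `"anger"`,
#'   `"sadness"`, or `NA`.
#' @param authenticity `"real"`, `"fake"`, or `NA`.
#' @param frame_index Optional integer vector of original 0-based frame
#'   numbers (defaults to `0:(n - 1)`); preserved when a trailing analysis
#'   window is extracted.
#' @return An object of class `landmark_stream`.
#' @export
landmark_stream <- function(coords, fps, subject = NA_character_,
                            emotion = NA_character_,
                            authenticity = NA_character_,
                            frame_index = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 136L) {
    stop("landmark stream needs 68 (x, y) points per frame, i.e. 136 columns; got ",
         ncol(coords), call. = FALSE)
  }
  if (nrow(coords) < 1L) stop("landmark stream has no frames", call. = FALSE)
  if (!all(is.finite(coords))) {
    stop("landmark coordinates must all be finite", call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop("fps must be a single positive number", call. = FALSE)
  }
  if (is.null(frame_index)) frame_index <- seq_len(nrow(coords)) - 1L
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != nrow(coords) || any(frame_index < 0L) ||
      any(diff(frame_index) != 1L)) {
    stop("frame_index must be non-negative, gap-free and match the frame count",
         call. = FALSE)
  }
  if (!is.na(emotion)) emotion <- match.arg(emotion, .emotions)
  if (!is.na(authenticity)) authenticity <- match.arg(authenticity, .authenticities)
  dimnames(coords) <- list(NULL, paste0(rep(c("x", "y"), 68), rep(0:67, each = 2)))
  structure(
    list(coords = coords, fps = fps, frame_index = frame_index,
         meta = list(subject = subject, emotion = emotion,
                     authenticity = authenticity)),
    class = "landmark_stream"
  )
}

#' @export
print.landmark_stream <- function(x, ...) {
  cat(sprintf(
    "<landmark_stream> %d frames @ %g fps (%.1f s)\n  subject: %s  emotion: %s  authenticity: %s\n",
    nrow(x$coords), x$fps, nrow(x$coords) / x$fps,
    x$meta$subject, x$meta$emotion, x$meta$authenticity
  ))
  invisible(x)
}

#' Stream duration in seconds
#' @param stream A `landmark_stream`.
#' @return Duration in seconds (`n_frames / fps`).
#' @export
stream_duration <- function(stream) {
  stopifnot(inherits(stream, "landmark_stream"))
  nrow(stream$coords) / stream$fps
}

# columns of landmark `idx0` (0-based label) in the coordinate matrix
.lm_cols <- function(idx0) c(2L * idx0 + 1L, 2L * idx0 + 2L)

#' Extract the trailing analysis window
#'
#' Recordings let the eliciting stimulus sink in before the cued expression;
#' only the final part of the stream is analysed (default 30 s). Original
#' frame indices and metadata are preserved.
#'
#' @param stream A `landmark_stream`.
#' @param window_s Window length in seconds (default 30).
#' @return A `landmark_stream` containing the last `round(window_s * fps)`
#'   frames.
#' @export
extract_analysis_window <- function(stream, window_s = 30) {
  stopifnot(inherits(stream, "landmark_stream"))
  n <- nrow(stream$coords)
  n_win <- round(window_s * stream$fps)
  if (n < n_win) {
    stop(sprintf(
      "stream too short for analysis window: %.2f s required, %.2f s available",
      window_s, n / stream$fps
    ), call. = FALSE)
  }
  keep <- seq.int(n - n_win + 1L, n)
  landmark_stream(stream$coords[keep, , drop = FALSE], stream$fps,
                  subject = stream$meta$subject, emotion = stream$meta$emotion,
                  authenticity = stream$meta$authenticity,
                  frame_index = stream$frame_index[keep])
}

#' Extract the eleven AU centroid trajectories
#'
#' Maps each frame's 68 landmarks to the 11 action-unit centroids.
#'
#' @param stream A `landmark_stream`.
#' @return A named list of 11 `au_trajectory` objects (fields `au`, `side`,
#'   `positions` — an `n x 2` matrix — and `fps`), in the order of
#'   [au_definitions()].
#' @export
extract_au_trajectories <- function(stream) {
  stopifnot(inherits(stream, "landmark_stream"))
  defs <- au_definitions()
  out <- vector("list", nrow(defs))
  names(out) <- defs$au
  for (i in seq_len(nrow(defs))) {
    idx <- defs$landmarks[[i]]
    cols <- vapply(idx, .lm_cols, integer(2))
    x <- rowMeans(stream$coords[, cols[1L, ], drop = FALSE])
    y <- rowMeans(stream$coords[, cols[2L, ], drop = FALSE])
    out[[i]] <- au_trajectory(cbind(x = x, y = y), au = defs$au[i],
                              side = defs$side[i], fps = stream$fps)
  }
  out
}

#' Construct an AU trajectory
#'
#' @param positions `n x 2` matrix of per-frame centroid positions.
#' @param au AU name.
#' @param side `"left"`, `"right"` or `"middle"`.
#' @param fps Sampling rate.
#' @return An `au_trajectory` object.
#' @export
au_trajectory <- function(positions, au, side, fps) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 2L, all(is.finite(positions)), fps > 0)
  structure(list(positions = positions, au = au, side = side, fps = fps),
            class = "au_trajectory")
}

#' @export
print.au_trajectory <- function(x, ...) {
  cat(sprintf("<au_trajectory> %s (%s), %d frames @ %g fps\n",
              x$au, x$side, nrow(x$positions), x$fps))
  invisible(x)
}
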