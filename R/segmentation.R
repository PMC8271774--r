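#' Scalar movement signal of an AU trajectory
#'
#' The thresholded quantity is the Euclidean displacement of the AU centroid
#' from a neutral baseline position, by default the mean centroid over the
#' first `baseline_s` seconds of the (windowed) trajectory. An optional
#' centred moving average suppresses single-frame jitter crossings before
#' thresholding.
#'
#' @param traj An `au_trajectory` (normally from the analysis window).
#' @param baseline Length-2 `(x, y)` baseline position; default: mean position
#'   over the first `baseline_s` seconds.
#' @param baseline_s Seconds used for the default baseline (default 1).
#' @param smooth Apply a `smooth_n`-frame centred moving average (default
#'   `TRUE`).
#' @param smooth_n Moving-average width in frames (default 5).
#' @return A `movement_signal` object with fields `values` (pixels), `fps`,
#'   `au`, `side` and `baseline`.
#' @export
movement_signal <- function(traj, baseline = NULL, baseline_s = 1,
                            smooth = TRUE, smooth_n = 5L) {
  stopifnot(inherits(traj, "au_trajectory"))
  pos <- traj$positions
  if (nrow(pos) < 2L) stop("trajectory has fewer than 2 frames", call. = FALSE)
  if (is.null(baseline)) {
    nb <- max(1L, min(nrow(pos), round(baseline_s * traj$fps)))
    baseline <- colMeans(pos[seq_len(nb), , drop = FALSE])
  }
  if (length(baseline) != 2L || !all(is.finite(baseline))) {
    stop("baseline must be a finite (x, y) point", call. = FALSE)
  }
  v <- sqrt((pos[, 1L] - baseline[1L])^2 + (pos[, 2L] - baseline[2L])^2)
  if (isTRUE(smooth) && smooth_n > 1L && length(v) >= smooth_n) {
    sm <- stats::filter(v, rep(1 / smooth_n, smooth_n), sides = 2)
    sm <- as.numeric(sm)
    sm[is.na(sm)] <- v[is.na(sm)]  # keep raw values at the edges
    v <- sm
  }
  structure(list(values = v, fps = traj$fps, au = traj$au, side = traj$side,
                 baseline = baseline),
            class = "movement_signal")
}

#' @export
print.movement_signal <- function(x, ...) {
  cat(sprintf("<movement_signal> %s, %d frames @ %g fps, range [%.3g, %.3g] px\n",
              x$au, length(x$values), x$fps, min(x$values), max(x$values)))
  invisible(x)
}

#' Min-max midrange threshold
#'
#' The onset threshold of a movement signal: `(max + min) / 2`. A constant
#' signal has no crossing; the returned value then carries
#' `attr(, "degenerate") = TRUE`.
#'
#' @param signal A `movement_signal` or numeric vector (length >= 2).
#' @return The threshold, with a logical `degenerate` attribute.
#' @export
minmax_threshold <- function(signal) {
  v <- if (inherits(signal, "movement_signal")) signal$values else signal
  if (length(v) < 2L) stop("signal needs at least 2 values", call. = FALSE)
  if (!all(is.finite(v))) stop("signal values must be finite", call. = FALSE)
  lo <- min(v)
  hi <- max(v)
  structure((hi + lo) / 2, degenerate = (hi == lo))
}

#' Detect expression onset
#'
#' The onset is the first frame whose movement value strictly exceeds the
#' min-max threshold. Frame indices are 1-based positions within the signal
#' (R convention; file formats use 0-based frame numbers).
#'
#' @param signal A `movement_signal` or numeric vector.
#' @param threshold Optional threshold; default [minmax_threshold()].
#' @return Integer onset frame (1-based).
#' @export
detect_onset <- function(signal, threshold = NULL) {
  v <- if (inherits(signal, "movement_signal")) signal$values else signal
  if (is.null(threshold)) threshold <- minmax_threshold(v)
  if (isTRUE(attr(threshold, "degenerate"))) {
    stop("constant movement signal: no onset exists", call. = FALSE)
  }
  idx <- which(v > as.numeric(threshold))[1L]
  if (is.na(idx)) stop("no frame exceeds the threshold", call. = FALSE)
  as.integer(idx)
}

#' Global onset across AUs
#'
#' The expression onset is treated as one event: the median of the per-AU
#' onset frames (AUs with degenerate, constant signals are skipped).
#'
#' @param signals List of `movement_signal` objects (one per AU).
#' @return Integer onset frame (1-based), or an error if every AU is
#'   degenerate.
#' @export
global_onset <- function(signals) {
  onsets <- vapply(signals, function(s) {
    tryCatch(as.numeric(detect_onset(s)), error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(onsets))) {
    stop("no AU has a detectable onset (all signals constant)", call. = FALSE)
  }
  as.integer(round(stats::median(onsets, na.rm = TRUE)))
}

#' Cut pre-onset and post-onset sections of a trajectory
#'
#' Produces the pre-onset micromovement section `[1, onset)` and three
#' post-onset sections all starting at the onset: 0.5 s and 1 s
#' (micromovement) and 4 s (macromovement). The post sections overlap by
#' construction and are nested when untruncated. Sections that run past the
#' end of the trajectory are truncated and flagged.
#'
#' @param traj An `au_trajectory`.
#' @param onset Onset frame (1-based) within the trajectory.
#' @param sections Named numeric vector of post-onset durations in seconds.
#' @return A `segmented_trajectory`: fields `au`, `side`, `fps`, `onset`,
#'   `pre` (`start`, `end`, `empty`) and `post`, a named list with `start`,
#'   `end`, `length` and `truncated` per section.
#' @export
segment_trajectory <- function(traj, onset,
                               sections = c("t+0.5" = 0.5, "t+1" = 1, "t+4" = 4)) {
  stopifnot(inherits(traj, "au_trajectory"))
  n <- nrow(traj$positions)
  onset <- as.integer(onset)
  if (onset < 1L || onset > n) {
    stop("onset ", onset, " outside trajectory of length ", n, call. = FALSE)
  }
  pre <- list(start = 1L, end = onset - 1L, empty = onset == 1L)
  post <- lapply(sections, function(d) {
    len <- as.integer(round(d * traj$fps))
    end_full <- onset + len - 1L
    end <- min(end_full, n)
    list(start = onset, end = end, length = end - onset + 1L,
         truncated = end_full > n)
  })
  structure(list(au = traj$au, side = traj$side, fps = traj$fps,
                 onset = onset, pre = pre, post = post),
            class = "segmented_trajectory")
}

#' @export
print.segmented_trajectory <- function(x, ...) {
  cat(sprintf("<segmented_trajectory> %s, onset frame %d\n", x$au, x$onset))
  cat(sprintf("  pre: [%d, %d]%s\n", x$pre$start, x$pre$end,
              if (x$pre$empty) " (empty)" else ""))
  for (nm in names(x$post)) {
    p <- x$post[[nm]]
    cat(sprintf("  %s: [%d, %d] (%d frames)%s\n", nm, p$start, p$end,
                p$length, if (p$truncated) " (truncated)" else ""))
  }
  invisible(x)
}

#' Tabulate segments of one or more AUs
#'
#' @param segments A `segmented_trajectory` or list of them.
#' @param meta Optional named list (`subject`, `emotion`, `authenticity`)
#'   prepended as columns.
#' @return A tibble with one row per section:
#'   `au, onset_frame, section, start, end, truncated`.
#' @export
segment_report <- function(segments, meta = NULL) {
  if (inherits(segments, "segmented_trajectory")) segments <- list(segments)
  rows <- lapply(segments, function(s) {
    tibble::tibble(
      au = s$au,
      onset_frame = s$onset,
      section = c("pre", names(s$post)),
      start = c(s$pre$start, vapply(s$post, `[[`, integer(1), "start")),
      end = c(s$pre$end, vapply(s$post, `[[`, integer(1), "end")),
      truncated = c(s$pre$empty, vapply(s$post, `[[`, logical(1), "truncated"))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(meta)) {
    out <- tibble::add_column(out,
      subject = meta$subject %||% NA_character_,
      emotion = meta$emotion %||% NA_character_,
      authenticity = meta$authenticity %||% NA_character_,
      .before = 1L)
  }
  out
}
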