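#' Frame-to-frame position deltas
#'
#' The per-frame change in AU coordination: `dx[n] = x[n-1] - x[n]` and
#' `dy[n] = y[n-1] - y[n]` (previous minus current), plus the Euclidean
#' magnitude `sqrt(dx^2 + dy^2)`. Feature summaries operate on the magnitude,
#' a single rotation-robust scalar per frame.
#'
#' @param positions `n x 2` matrix of positions, or an `au_trajectory`.
#' @param fps Sampling rate; taken from the trajectory when given.
#' @return A `delta_series` with fields `dx`, `dy`, `magnitude` (all length
#'   `n - 1`) and `fps`.
#' @export
frame_deltas <- function(positions, fps = NULL) {
  if (inherits(positions, "au_trajectory")) {
    if (is.null(fps)) fps <- positions$fps
    positions <- positions$positions
  }
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2L) stop("need at least 2 frames to compute deltas", call. = FALSE)
  dx <- positions[-n, 1L] - positions[-1L, 1L]
  dy <- positions[-n, 2L] - positions[-1L, 2L]
  structure(list(dx = unname(dx), dy = unname(dy),
                 magnitude = unname(sqrt(dx^2 + dy^2)), fps = fps),
            class = "delta_series")
}

#' @export
print.delta_series <- function(x, ...) {
  cat(sprintf("<delta_series> %d deltas, mean |d| = %.4g px/frame\n",
              length(x$magnitude), mean(x$magnitude)))
  invisible(x)
}

#' Mean and standard deviation of the delta magnitude
#'
#' Degree and variance of movement. The SD uses the population convention
#' (divide by n) by default.
#'
#' @param deltas A `delta_series` or numeric magnitude vector.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return Named numeric vector `c(mean, sd)` in pixels/frame.
#' @export
delta_summary <- function(deltas, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  v <- if (inherits(deltas, "delta_series")) deltas$magnitude else deltas
  if (length(v) < 1L) stop("empty delta series", call. = FALSE)
  m <- mean(v)
  s <- if (sd_type == "population") {
    sqrt(mean((v - m)^2))
  } else {
    stats::sd(v)
  }
  c(mean = m, sd = s)
}

#' Dominant spectral peak frequency of a delta series
#'
#' Vibration level: the frequency of the maximum-magnitude discrete-spectrum
#' bin of the mean-removed delta-magnitude series, searched within `band`.
#' The default band starts at 2 Hz — micromovement vibration periods are
#' 0.04–0.5 s, i.e. 2–25 Hz — which also excludes DC and slow drift from the
#' expression ramp; it ends at the Nyquist frequency. Ties break toward the
#' lower frequency.
#'
#' @param deltas A `delta_series`, or a numeric series with `fps` supplied.
#' @param fps Sampling rate (frames/s); taken from `deltas` when available.
#' @param band Length-2 Hz interval searched (default `c(2, fps / 2)`).
#' @param min_frames Minimum series length for a stable estimate (default 8);
#'   shorter input yields `NA` with a `reason` attribute.
#' @param window `"none"` (default) or `"hann"` taper before the transform.
#' @return Peak frequency in Hz, or `NA_real_` (with `attr(, "reason")`) when
#'   the series is too short or the in-band spectrum is identically zero.
#' @export
dominant_peak_frequency <- function(deltas, fps = NULL, band = NULL,
                                    min_frames = 8L,
                                    window = c("none", "hann")) {
  window <- match.arg(window)
  if (inherits(deltas, "delta_series")) {
    if (is.null(fps)) fps <- deltas$fps
    v <- deltas$magnitude
  } else {
    v <- as.numeric(deltas)
  }
  if (is.null(fps) || !is.finite(fps) || fps <= 0) {
    stop("fps must be supplied and positive", call. = FALSE)
  }
  n <- length(v)
  if (n < min_frames) {
    return(structure(NA_real_, reason = sprintf(
      "series too short for spectral estimate (%d < %d frames)", n, min_frames)))
  }
  if (is.null(band)) band <- c(2, fps / 2)
  x <- v - mean(v)
  if (window == "hann") {
    x <- x * (0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1)))
  }
  spec <- Mod(stats::fft(x))
  k <- seq_len(floor(n / 2))          # positive frequencies, DC excluded
  freqs <- k * fps / n
  sel <- freqs >= band[1L] & freqs <= band[2L]
  if (!any(sel)) {
    return(structure(NA_real_, reason = "no spectral bins inside the band"))
  }
  mags <- spec[k + 1L][sel]
  if (max(mags) < 1e-10) {
    return(structure(NA_real_, reason = "spectrum identically zero in band"))
  }
  freqs[sel][which.max(mags)]          # which.max -> first, i.e. lowest, on ties
}

#' Full feature table for one recording
#'
#' Runs the pipeline on one landmark stream: trailing analysis window ->
#' 11 AU centroid trajectories -> movement signals -> min-max onset
#' (a single global onset, the median across AUs, by default) -> pre and
#' post sections -> the three feature variables per AU x section.
#'
#' @param stream A `landmark_stream`.
#' @param window_s Analysis-window length in seconds (default 30).
#' @param sections Named post-onset durations in seconds.
#' @param global Use one shared onset across AUs (default `TRUE`); otherwise
#'   each AU uses its own onset.
#' @param baseline_s,smooth,smooth_n Passed to [movement_signal()].
#' @param band_low Lower edge (Hz) of the spectral peak search band.
#' @param sd_type SD convention, see [delta_summary()].
#' @return A tibble with one row per AU x section (11 x 4 = 44 rows):
#'   `subject, emotion, authenticity, au, side, section, onset_frame,
#'   n_frames, truncated, mean_delta, sd_delta, dominant_peak_hz`.
#'   Sections with fewer than 2 frames have `NA` features.
#' @export
feature_table <- function(stream, window_s = 30,
                          sections = c("t+0.5" = 0.5, "t+1" = 1, "t+4" = 4),
                          global = TRUE, baseline_s = 1, smooth = TRUE,
                          smooth_n = 5L, band_low = 2,
                          sd_type = "population") {
  stopifnot(inherits(stream, "landmark_stream"))
  win <- extract_analysis_window(stream, window_s)
  trajs <- extract_au_trajectories(win)
  sigs <- lapply(trajs, movement_signal, baseline_s = baseline_s,
                 smooth = smooth, smooth_n = smooth_n)
  onset_global <- if (global) global_onset(sigs) else NA_integer_
  fps <- win$fps
  sec_names <- c("pre", names(sections))
  n_au <- length(trajs)
  n_rows <- n_au * length(sec_names)
  au_v <- side_v <- sec_v <- character(n_rows)
  onset_v <- nf_v <- integer(n_rows)
  trunc_v <- logical(n_rows)
  mean_v <- sd_v <- peak_v <- rep(NA_real_, n_rows)
  r_i <- 0L
  for (i in seq_along(trajs)) {
    traj <- trajs[[i]]
    onset <- if (global) onset_global else
      tryCatch(detect_onset(sigs[[i]]), error = function(e) NA_integer_)
    if (is.na(onset)) {
      idx <- r_i + seq_along(sec_names)
      au_v[idx] <- traj$au; side_v[idx] <- traj$side
      sec_v[idx] <- sec_names
      onset_v[idx] <- NA_integer_; nf_v[idx] <- NA_integer_
      trunc_v[idx] <- NA
      r_i <- r_i + length(sec_names)
      next
    }
    seg <- segment_trajectory(traj, onset, sections)
    ranges <- c(list(pre = c(seg$pre$start, seg$pre$end, seg$pre$empty)),
                lapply(seg$post, function(p) c(p$start, p$end, p$truncated)))
    for (nm in sec_names) {
      r <- ranges[[nm]]
      nf <- if (nm == "pre" && r[3L]) 0L else r[2L] - r[1L] + 1L
      r_i <- r_i + 1L
      au_v[r_i] <- traj$au; side_v[r_i] <- traj$side; sec_v[r_i] <- nm
      onset_v[r_i] <- onset; nf_v[r_i] <- as.integer(nf)
      trunc_v[r_i] <- as.logical(r[3L])
      if (nf >= 2L) {
        d <- frame_deltas(traj$positions[r[1L]:r[2L], , drop = FALSE], fps = fps)
        ms <- delta_summary(d, sd_type = sd_type)
        mean_v[r_i] <- ms[["mean"]]
        sd_v[r_i] <- ms[["sd"]]
        peak_v[r_i] <- as.numeric(
          dominant_peak_frequency(d, band = c(band_low, fps / 2)))
      }
    }
  }
  tibble::tibble(
    subject = stream$meta$subject %||% NA_character_,
    emotion = stream$meta$emotion %||% NA_character_,
    authenticity = stream$meta$authenticity %||% NA_character_,
    au = au_v, side = side_v, section = sec_v, onset_frame = onset_v,
    n_frames = nf_v, truncated = trunc_v, mean_delta = mean_v,
    sd_delta = sd_v, dominant_peak_hz = peak_v)
}

#' Write a feature table to CSV
#' @param features Tibble from [feature_table()] (or several bound together).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
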