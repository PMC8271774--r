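#' HRV frequency bands
#'
#' Very-low-frequency (VLF), low-frequency (LF) and high-frequency (HF)
#' bands of the RR-interval spectrum. HF indexes parasympathetic activity;
#' VLF is read here as autonomic arousal. Bands are half-open `[low, high)`.
#'
#' @return Tibble with columns `band`, `low`, `high` (Hz).
#' @export
hrv_bands <- function() {
  tibble::tibble(
    band = c("vlf", "lf", "hf"),
    low = c(0.003, 0.04, 0.15),
    high = c(0.04, 0.15, 0.4)
  )
}

#' Construct an RR-interval series
#'
#' Successive R-R intervals in seconds. Intervals outside `(0.3, 2)` s are
#' physiologically implausible beats and are removed with a warning.
#'
#' @param intervals Numeric vector of intervals (seconds).
#' @param subject,condition Metadata labels.
#' @param clean Remove out-of-range intervals (default `TRUE`).
#' @param range Plausible interval range in seconds.
#' @return An `rr_series` with fields `intervals` and `meta`.
#' @export
rr_series <- function(intervals, subject = NA_character_,
                      condition = NA_character_, clean = TRUE,
                      range = c(0.3, 2)) {
  intervals <- as.numeric(intervals)
  if (anyNA(intervals)) intervals <- intervals[!is.na(intervals)]
  if (clean) {
    bad <- intervals <= range[1L] | intervals >= range[2L]
    if (any(bad)) {
      warning(sum(bad), " RR interval(s) outside (", range[1L], ", ", range[2L],
              ") s removed", call. = FALSE)
      intervals <- intervals[!bad]
    }
  }
  if (length(intervals) < 2L) {
    stop("RR series needs at least 2 intervals after cleaning", call. = FALSE)
  }
  structure(list(intervals = intervals,
                 meta = list(subject = subject, condition = condition)),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d intervals spanning %.1f s (mean RR %.0f ms)\n",
              length(x$intervals), sum(x$intervals),
              mean(x$intervals) * 1000))
  invisible(x)
}

#' VLF/LF/HF band powers of an RR series
#'
#' The RR series is laid out at its cumulative beat times (tachogram, in ms),
#' resampled to an evenly spaced grid by cubic spline interpolation (4 Hz),
#' mean-removed, and transformed with the FFT. Band power is the integrated
#' spectral power inside each band; a pure sinusoid of amplitude `a` ms
#' contributes `a^2 / 2` ms^2. Percentages are relative to the three-band sum
#' (the overall power), so they close to 100.
#'
#' @param rr An `rr_series` (or numeric interval vector in seconds).
#' @param resample_hz Tachogram resampling rate (default 4 Hz).
#' @param min_span_s Minimum series span in seconds (default 60).
#' @return One-row tibble: `vlf, lf, hf` (ms^2), `vlf_pct, lf_pct, hf_pct`
#'   (%), and `total` (ms^2, the three-band sum).
#' @export
hrv_band_powers <- function(rr, resample_hz = 4, min_span_s = 60) {
  if (!inherits(rr, "rr_series")) rr <- rr_series(rr)
  int <- rr$intervals
  span <- sum(int)
  if (span < min_span_s) {
    stop(sprintf("RR series spans %.1f s; at least %g s required",
                 span, min_span_s), call. = FALSE)
  }
  t_beat <- cumsum(int)
  v <- int * 1000                                   # tachogram in ms
  grid <- seq(t_beat[1L], t_beat[length(t_beat)], by = 1 / resample_hz)
  y <- stats::spline(t_beat, v, xout = grid)$y
  y <- y - mean(y)
  n <- length(y)
  spec <- Mod(stats::fft(y))^2
  k <- seq_len(floor(n / 2))
  freqs <- k * resample_hz / n
  pow <- 2 * spec[k + 1L] / n^2                     # per-bin variance (ms^2)
  bands <- hrv_bands()
  bp <- vapply(seq_len(nrow(bands)), function(i) {
    sum(pow[freqs >= bands$low[i] & freqs < bands$high[i]])
  }, numeric(1))
  names(bp) <- bands$band
  total <- sum(bp)
  pct <- if (total > 0) 100 * bp / total else rep(NA_real_, 3L)
  if (total == 0) warning("total in-band power is zero; percentages undefined",
                          call. = FALSE)
  tibble::tibble(
    vlf = bp[["vlf"]], lf = bp[["lf"]], hf = bp[["hf"]],
    vlf_pct = pct[[1L]], lf_pct = pct[[2L]], hf_pct = pct[[3L]],
    total = total
  )
}

#' Sliding-window HRV time course
#'
#' Band powers over successive windows of `window_s` seconds anchored at
#' window ends `window_s, window_s + step_s, ...` up to the series span.
#'
#' @param rr An `rr_series`.
#' @param window_s Window length in seconds (default 180).
#' @param step_s Step between window ends in seconds (default 10).
#' @param ... Passed to [hrv_band_powers()].
#' @return Tibble with one row per window; `t_end` gives the window end in
#'   seconds. A series shorter than `window_s` yields a single whole-series
#'   window with a warning.
#' @export
sliding_hrv <- function(rr, window_s = 180, step_s = 10, ...) {
  stopifnot(inherits(rr, "rr_series"))
  t_beat <- cumsum(rr$intervals)
  span <- t_beat[length(t_beat)]
  if (span < window_s) {
    warning(sprintf(
      "series spans %.1f s < window of %g s; returning a single whole-series window",
      span, window_s), call. = FALSE)
    out <- hrv_band_powers(rr, ...)
    return(tibble::add_column(out, t_end = span, .before = 1L))
  }
  ends <- seq(window_s, span + 1e-9, by = step_s)
  rows <- lapply(ends, function(e) {
    sel <- t_beat > (e - window_s) & t_beat <= e + 1e-9
    sub <- rr_series(rr$intervals[sel], clean = FALSE)
    tibble::add_column(hrv_band_powers(sub, ...), t_end = e, .before = 1L)
  })
  dplyr::bind_rows(rows)
}

#' R-peak detection from raw single-channel ECG
#'
#' Convenience stage for recordings that provide raw ECG rather than RR
#' intervals: 5-15 Hz Butterworth band-pass, squared and smoothed energy
#' envelope, adaptive threshold at half the 99.5th percentile, local maxima
#' with a 0.3-s refractory period. Successive peak-time differences become
#' the RR series.
#'
#' @param ecg Numeric voltage series.
#' @param fs Sampling rate in Hz (default 500; must be >= 100).
#' @param band Band-pass edges in Hz.
#' @param refractory_s Minimum inter-peak distance in seconds.
#' @param ... Passed to [rr_series()].
#' @return An `rr_series` with an attribute `peak_times_s` (detected R-peak
#'   times in seconds).
#' @export
rr_from_ecg <- function(ecg, fs = 500, band = c(5, 15), refractory_s = 0.3,
                        ...) {
  ecg <- as.numeric(ecg)
  if (fs < 100) stop("sampling rate must be at least 100 Hz", call. = FALSE)
  if (length(ecg) < fs) stop("ECG shorter than one second", call. = FALSE)
  bf <- signal::butter(3, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, ecg)
  w <- round(0.1 * fs)
  if (w %% 2 == 0) w <- w + 1                       # odd width: no phase shift
  env <- as.numeric(stats::filter(y^2, rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0
  thr <- 0.5 * stats::quantile(env, 0.995, names = FALSE)
  if (!is.finite(thr) || thr <= 0) stop("no R peaks found", call. = FALSE)
  above <- env > thr
  n <- length(env)
  is_max <- above & env >= c(-Inf, env[-n]) & env > c(env[-1L], -Inf)
  cand <- which(is_max)
  if (length(cand) == 0L) stop("no R peaks found", call. = FALSE)
  refr <- refractory_s * fs
  peaks <- cand[1L]
  for (i in cand[-1L]) {
    last <- peaks[length(peaks)]
    if (i - last >= refr) {
      peaks <- c(peaks, i)
    } else if (env[i] > env[last]) {
      peaks[length(peaks)] <- i                     # keep the larger of a close pair
    }
  }
  if (length(peaks) < 2L) stop("fewer than 2 R peaks detected", call. = FALSE)
  times <- (peaks - 1) / fs
  out <- rr_series(diff(times), ...)
  attr(out, "peak_times_s") <- times
  out
}

#' Write HRV results to CSV with Table-style variable names
#' @param hrv Tibble from [hrv_band_powers()] or [sliding_hrv()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_hrv_csv <- function(hrv, path) {
  nm <- c(vlf = "VLF", lf = "LF", hf = "HF",
          vlf_pct = "VLF (%)", lf_pct = "LF (%)", hf_pct = "HF (%)")
  out <- hrv
  names(out) <- ifelse(names(out) %in% names(nm), nm[names(out)], names(out))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
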