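#' Schematic neutral 68-point face template
#'
#' A fixed frontal-face landmark layout in a 1280 x 980 pixel frame
#' (y increasing downward), following the standard 68-point annotation order:
#' jawline 0-16, eyebrows 17-26, nose 27-35, eyes 36-47, outer lips 48-59,
#' inner lips 60-67. The exact coordinates are an artifact constant of the
#' generator, chosen to be anatomically plausible; nothing downstream depends
#' on them beyond the AU side geometry.
#'
#' @param width,height Frame size in pixels.
#' @return A 68 x 2 matrix of `(x, y)` coordinates (rows are 0-based landmark
#'   labels 0-67).
#' @export
neutral_face_template <- function(width = 1280, height = 980) {
  cx <- width / 2
  cy <- height / 2
  pts <- matrix(NA_real_, 68L, 2L)
  # jawline 0-16: ear - chin - ear arc
  a <- seq(pi, 2 * pi, length.out = 17)
  pts[1:17, ] <- cbind(cx + 300 * cos(a), (cy - 80) - 330 * sin(a))
  # eyebrows 17-21 (viewer left) and 22-26 (viewer right), gentle arch
  arch <- 15 * sin(seq(0, pi, length.out = 5))
  pts[18:22, ] <- cbind(seq(460, 600, length.out = 5), 330 - arch)
  pts[23:27, ] <- cbind(seq(680, 820, length.out = 5), 330 - arch)
  # nose bridge 27-30 and nostril line 31-35
  pts[28:31, ] <- cbind(rep(cx, 4), seq(355, 465, length.out = 4))
  pts[32:36, ] <- cbind(cx + c(-42, -21, 0, 21, 42), rep(495, 5))
  # eyes 36-41 (viewer left) and 42-47 (viewer right): 6-point hexagons
  eye <- function(ex, ey, rx = 48, ry = 16) {
    rbind(c(ex - rx, ey), c(ex - rx / 2, ey - ry), c(ex + rx / 2, ey - ry),
          c(ex + rx, ey), c(ex + rx / 2, ey + ry), c(ex - rx / 2, ey + ry))
  }
  pts[37:42, ] <- eye(520, 385)
  pts[43:48, ] <- eye(760, 385)
  # outer lips 48-59 and inner lips 60-67: ellipses
  mouth <- function(rx, ry, n_up, n_low, mx = cx, my = 620) {
    up <- seq(pi, 0, length.out = n_up)
    low <- seq(0, pi, length.out = n_low + 2)[2:(n_low + 1)]
    rbind(cbind(mx + rx * cos(up), my - ry * sin(up)),
          cbind(mx + rx * cos(low), my + ry * sin(low)))
  }
  pts[49:60, ] <- mouth(95, 42, 7, 5)
  pts[61:68, ] <- mouth(60, 16, 5, 3)
  colnames(pts) <- c("x", "y")
  pts
}

#' Expression profile: programmable ground truth for one condition
#'
#' Describes the cued expression the generator injects into the final part of
#' a landmark stream: a sigmoid onset ramp of `amplitude` pixels along each
#' active AU's outward direction, superposed with a micromovement tremor at
#' `vib_freq` Hz (physiological vibration periods are 0.04-0.5 s, i.e.
#' 2-25 Hz). The tremor is modelled as muscle twitches whose speed — the
#' frame-to-frame displacement magnitude, the very quantity the spectral
#' feature analyses — is a raised cosine at `vib_freq` with peak
#' `vib_amplitude` px/frame, while the movement direction alternates at the
#' speed zeros, keeping the landmark position bounded. The delta-magnitude
#' series of such motion is spectrally pure at `vib_freq` (a bidirectional
#' positional sinusoid would instead fold its energy onto harmonics through
#' the magnitude rectification), so the generator truth is recoverable by
#' the dominant-peak feature. Left-side AUs are scaled by `asymmetry`.
#'
#' @param emotion One of `"happiness"`, `"contentment"`, `"anger"`,
#'   `"sadness"`.
#' @param amplitude Onset displacement in pixels; scalar or named per-AU
#'   vector (names as in [au_definitions()]).
#' @param vib_amplitude Peak twitch speed in px/frame (scalar or per-AU).
#' @param vib_freq Vibration frequency in Hz, in (0, 25] (scalar or per-AU).
#' @param asymmetry Multiplier applied to left-side AU amplitudes
#'   (default 1.15).
#' @param ramp_s Onset ramp duration in seconds (default 1).
#' @param noise_sd Per-landmark, per-frame Gaussian jitter SD in pixels
#'   (default 0.3).
#' @return An `expression_profile`.
#' @export
expression_profile <- function(emotion, amplitude = 6, vib_amplitude = 1.5,
                               vib_freq = 8, asymmetry = 1.15, ramp_s = 1,
                               noise_sd = 0.3) {
  emotion <- match.arg(emotion, .emotions)
  aus <- au_definitions()$au
  expand_au <- function(x, what) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- stats::setNames(rep(as.numeric(x), 11L), aus)
    }
    if (!all(aus %in% names(x))) {
      stop(what, " must be an unnamed scalar or a vector named by the 11 AUs",
           call. = FALSE)
    }
    x[aus]
  }
  amplitude <- expand_au(amplitude, "amplitude")
  vib_amplitude <- expand_au(vib_amplitude, "vib_amplitude")
  vib_freq <- expand_au(vib_freq, "vib_freq")
  if (any(amplitude < 0) || any(vib_amplitude < 0)) {
    stop("amplitudes must be non-negative", call. = FALSE)
  }
  if (any(vib_freq <= 0) || any(vib_freq > 25)) {
    stop("vib_freq must be in (0, 25] Hz", call. = FALSE)
  }
  if (ramp_s <= 0) stop("ramp_s must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(list(emotion = emotion, amplitude = amplitude,
                 vib_amplitude = vib_amplitude, vib_freq = vib_freq,
                 asymmetry = asymmetry, ramp_s = ramp_s, noise_sd = noise_sd),
            class = "expression_profile")
}

#' Default real/fake expression profiles per emotion
#'
#' Illustrative defaults encoding the qualitative contrast the analysis is
#' built to detect: larger onset movement in the real condition for every
#' emotion, with the contrast strongest for happiness and anger; for the
#' low-arousal emotions (contentment, sadness), faster vibration in the fake
#' condition, so the dominant-peak feature separates the conditions in the
#' opposite direction. Effect sizes are free parameters of the generator,
#' not measured quantities.
#'
#' @return Named list: `profiles[[emotion]]$real` / `$fake`, each an
#'   [expression_profile()].
#' @export
default_profiles <- function() {
  list(
    happiness = list(
      real = expression_profile("happiness", amplitude = 8,
                                vib_amplitude = 1.8, vib_freq = 9),
      fake = expression_profile("happiness", amplitude = 5,
                                vib_amplitude = 1.2, vib_freq = 6)),
    contentment = list(
      real = expression_profile("contentment", amplitude = 5,
                                vib_amplitude = 1.5, vib_freq = 4),
      fake = expression_profile("contentment", amplitude = 4,
                                vib_amplitude = 0.7, vib_freq = 11)),
    anger = list(
      real = expression_profile("anger", amplitude = 9,
                                vib_amplitude = 2.0, vib_freq = 10),
      fake = expression_profile("anger", amplitude = 6,
                                vib_amplitude = 1.4, vib_freq = 7)),
    sadness = list(
      real = expression_profile("sadness", amplitude = 5,
                                vib_amplitude = 1.5, vib_freq = 4),
      fake = expression_profile("sadness", amplitude = 4,
                                vib_amplitude = 0.7, vib_freq = 12))
  )
}

#' Generate one synthetic landmark stream
#'
#' A neutral face template with per-landmark Gaussian jitter; from the ramp
#' midpoint `onset_s` onward, the landmarks of every AU move outward along
#' the radial direction from the face centre following a sigmoid ramp to the
#' profile amplitude, superposed with the profile's twitch-train vibration
#' (both gated by the ramp, so the pre-onset stream is quiet). Landmarks
#' shared by two AUs accumulate both displacements. Deterministic under
#' `seed`.
#'
#' @param profile An [expression_profile()].
#' @param fps Frames per second (default 30).
#' @param duration_s Stream duration in seconds (default 210: the recording
#'   length, of which the last 30 s contain the cued expression).
#' @param onset_s Ramp midpoint in seconds from stream start (default
#'   `duration_s - 15`: the middle of the final 30-s analysis window).
#' @param subject Subject label.
#' @param authenticity `"real"` or `"fake"` label for the stream metadata.
#' @param amp_multiplier Subject-level amplitude multiplier (default 1).
#' @param seed Optional integer seed.
#' @return A `landmark_stream` with attribute `ground_truth` (list with
#'   `onset_s`, `onset_frame` — 1-based within the default 30-s window —
#'   `vib_freq`, `amplitude`).
#' @export
generate_stream <- function(profile, fps = 30, duration_s = 210,
                            onset_s = duration_s - 15, subject = "s01",
                            authenticity = NA_character_,
                            amp_multiplier = 1, seed = NULL) {
  stopifnot(inherits(profile, "expression_profile"))
  if (any(profile$vib_freq >= fps / 2)) {
    stop("vib_freq must be below the Nyquist frequency fps/2", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fps)
  t <- (seq_len(n) - 1L) / fps
  base <- neutral_face_template()
  coords <- matrix(rep(t(base), n), nrow = n, byrow = TRUE)  # n x 136, x0 y0 ...
  if (profile$noise_sd > 0) {
    coords <- coords + matrix(stats::rnorm(n * 136L, 0, profile$noise_sd),
                              n, 136L)
  }
  centre <- c(640, 490)
  sig <- stats::plogis((t - onset_s) / (profile$ramp_s / 8))
  defs <- au_definitions()
  for (i in seq_len(nrow(defs))) {
    au <- defs$au[i]
    lr <- if (defs$side[i] == "left") profile$asymmetry else 1
    amp <- profile$amplitude[[au]] * amp_multiplier * lr
    vamp <- profile$vib_amplitude[[au]] * amp_multiplier * lr
    vf <- profile$vib_freq[[au]]
    if (amp == 0 && vamp == 0) next
    centroid <- colMeans(base[defs$landmarks[[i]] + 1L, , drop = FALSE])
    u <- centroid - centre
    u <- if (sum(u^2) > 0) u / sqrt(sum(u^2)) else c(0, -1)
    # twitch train: per-frame speed is a raised cosine at vf (px/frame),
    # direction alternates at the speed zeros -> bounded position, and the
    # delta-magnitude series is spectrally pure at vf
    speed <- (vamp / 2) * (1 + cos(2 * pi * vf * (t - onset_s))) * sig
    dir_sign <- ifelse(cos(pi * vf * (t - onset_s)) >= 0, 1, -1)
    vib <- cumsum(speed * dir_sign)
    disp <- amp * sig + vib
    for (l in defs$landmarks[[i]]) {
      cols <- .lm_cols(l)
      coords[, cols[1L]] <- coords[, cols[1L]] + disp * u[1L]
      coords[, cols[2L]] <- coords[, cols[2L]] + disp * u[2L]
    }
  }
  out <- landmark_stream(coords, fps, subject = subject,
                         emotion = profile$emotion,
                         authenticity = authenticity)
  attr(out, "ground_truth") <- list(
    onset_s = onset_s,
    onset_frame = round(onset_s * fps) - (n - round(30 * fps)),
    vib_freq = profile$vib_freq,
    amplitude = profile$amplitude * amp_multiplier)
  out
}

#' Generate a synthetic RR-interval series with programmed band shares
#'
#' Base interval 0.8 s, modulated by one sinusoid per HRV band at the band's
#' geometric-centre frequency, with amplitudes set so the modulation power
#' splits into the requested VLF/LF/HF shares, plus white beat-to-beat noise.
#' Beat times advance by the instantaneous interval, so the tachogram carries
#' the programmed spectrum. Deterministic under `seed`.
#'
#' @param shares Length-3 vector of VLF/LF/HF power fractions summing to 1
#'   (order `vlf, lf, hf`).
#' @param duration_s Series span in seconds (default 210).
#' @param base_rr_s Mean RR interval in seconds (default 0.8).
#' @param mod_sd_ms Total modulation SD in ms (default 40); total modulation
#'   power is `mod_sd_ms^2`.
#' @param noise_sd_ms White-noise SD per beat in ms (default 2).
#' @param subject,condition Metadata labels.
#' @param seed Optional integer seed.
#' @return An `rr_series` with attribute `ground_truth` (the programmed
#'   shares and component frequencies).
#' @export
generate_rr <- function(shares, duration_s = 210, base_rr_s = 0.8,
                        mod_sd_ms = 40, noise_sd_ms = 2,
                        subject = NA_character_, condition = NA_character_,
                        seed = NULL) {
  shares <- as.numeric(shares)
  if (length(shares) != 3L || any(shares < 0) ||
      abs(sum(shares) - 1) > 1e-8) {
    stop("shares must be 3 non-negative fractions summing to 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  b <- hrv_bands()
  freqs <- sqrt(b$low * b$high)                     # geometric band centres
  amps <- sqrt(2 * mod_sd_ms^2 * shares)            # sinusoid a^2/2 = share * P
  phases <- stats::runif(3L, 0, 2 * pi)
  n_max <- ceiling(duration_s / (base_rr_s * 0.5)) + 10L
  noise <- stats::rnorm(n_max, 0, noise_sd_ms)
  intervals <- numeric(n_max)
  t_now <- 0
  k <- 0L
  while (t_now < duration_s) {
    k <- k + 1L
    rr_ms <- base_rr_s * 1000 +
      sum(amps * sin(2 * pi * freqs * t_now + phases)) + noise[k]
    rr_ms <- max(rr_ms, 300.5)                      # keep within plausible range
    intervals[k] <- rr_ms / 1000
    t_now <- t_now + intervals[k]
  }
  out <- rr_series(intervals[seq_len(k)], subject = subject,
                   condition = condition)
  attr(out, "ground_truth") <- list(shares = shares, freqs = freqs,
                                    mod_sd_ms = mod_sd_ms)
  out
}

#' Generate a synthetic single-channel ECG with known R-peak times
#'
#' Gaussian R-wave pulses at the given peak times over a slow baseline
#' wander plus measurement noise; a convenience input for exercising
#' [rr_from_ecg()] against generator-known truth.
#'
#' @param peak_times_s R-peak times in seconds (or an `rr_series`, whose
#'   cumulative beat times are used).
#' @param fs Sampling rate in Hz (default 500).
#' @param duration_s Signal duration (default: last peak + 0.5 s).
#' @param amplitude R-wave amplitude (default 1).
#' @param width_s Gaussian R-wave SD in seconds (default 0.012).
#' @param noise_sd Additive noise SD (default 0.01).
#' @param seed Optional integer seed.
#' @return Numeric voltage vector with attributes `fs` and `peak_times_s`.
#' @export
generate_ecg <- function(peak_times_s, fs = 500, duration_s = NULL,
                         amplitude = 1, width_s = 0.012, noise_sd = 0.01,
                         seed = NULL) {
  if (inherits(peak_times_s, "rr_series")) {
    peak_times_s <- cumsum(peak_times_s$intervals)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(duration_s)) duration_s <- max(peak_times_s) + 0.5
  t <- seq(0, duration_s, by = 1 / fs)
  y <- 0.05 * sin(2 * pi * 0.25 * t)                # baseline wander
  for (tp in peak_times_s) {
    win <- which(abs(t - tp) < 6 * width_s)
    y[win] <- y[win] + amplitude * exp(-(t[win] - tp)^2 / (2 * width_s^2))
  }
  if (noise_sd > 0) y <- y + stats::rnorm(length(t), 0, noise_sd)
  structure(y, fs = fs, peak_times_s = peak_times_s)
}

#' Cohort specification
#'
#' The design of a simulated study: `n_subjects` participants, each recorded
#' once per emotion x authenticity combination (within-subject), with
#' condition-specific expression profiles and HRV band-share vectors, and a
#' lognormal subject-level amplitude multiplier.
#'
#' @param n_subjects Number of subjects (default 40, the analysed sample).
#' @param fps Frames per second (default 30).
#' @param duration_s Recording length in seconds (default 210).
#' @param window_s Analysis-window length (default 30).
#' @param onset_s Ramp midpoint in seconds (default `duration_s - 15`).
#' @param emotions Emotions simulated (default all four).
#' @param profiles Named list `profiles[[emotion]]$real/$fake` of
#'   [expression_profile()]s (default [default_profiles()]).
#' @param hrv_shares Named list `real`/`fake` of VLF/LF/HF share vectors.
#' @param hrv_mod_sd_ms Named list `real`/`fake` of total modulation SD (ms).
#' @param subject_sd SD of the lognormal subject amplitude multiplier
#'   (default 0.2).
#' @param seed Integer seed; a fixed seed gives bit-identical cohorts.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 40, fps = 30, duration_s = 210,
                        window_s = 30, onset_s = duration_s - 15,
                        emotions = c("happiness", "contentment", "anger",
                                     "sadness"),
                        profiles = NULL,
                        hrv_shares = list(real = c(0.45, 0.28, 0.27),
                                          fake = c(0.25, 0.28, 0.47)),
                        hrv_mod_sd_ms = list(real = 40, fake = 50),
                        subject_sd = 0.2, seed = 1L) {
  emotions <- match.arg(emotions, .emotions, several.ok = TRUE)
  if (is.null(profiles)) profiles <- default_profiles()[emotions]
  stopifnot(all(emotions %in% names(profiles)))
  for (em in emotions) {
    stopifnot(inherits(profiles[[em]]$real, "expression_profile"),
              inherits(profiles[[em]]$fake, "expression_profile"))
  }
  for (cond in c("real", "fake")) {
    if (abs(sum(hrv_shares[[cond]]) - 1) > 1e-8) {
      stop("hrv_shares$", cond, " must sum to 1", call. = FALSE)
    }
  }
  structure(list(n_subjects = as.integer(n_subjects), fps = fps,
                 duration_s = duration_s, window_s = window_s,
                 onset_s = onset_s, emotions = emotions, profiles = profiles,
                 hrv_shares = hrv_shares, hrv_mod_sd_ms = hrv_mod_sd_ms,
                 subject_sd = subject_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d subjects x %d emotions x 2 conditions = %d recordings\n",
    x$n_subjects, length(x$emotions),
    x$n_subjects * length(x$emotions) * 2L))
  cat(sprintf("  %g s @ %g fps, analysis window %g s, onset at %g s, seed %d\n",
              x$duration_s, x$fps, x$window_s, x$onset_s, x$seed))
  invisible(x)
}

#' Cohort manifest: one row per recording, with full ground truth
#'
#' Deterministic under the spec seed; per-recording seeds are derived from it
#' so any single recording can be regenerated independently.
#'
#' @param spec A [cohort_spec()].
#' @return Tibble: `recording, subject, emotion, authenticity,
#'   amp_multiplier, onset_s, stream_seed, rr_seed` plus the programmed
#'   `vlf/lf/hf` shares.
#' @export
cohort_manifest <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  mult <- stats::rlnorm(spec$n_subjects, 0, spec$subject_sd)
  grid <- expand.grid(authenticity = .authenticities,
                      emotion = spec$emotions,
                      subject_i = seq_len(spec$n_subjects),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("subject_i", "emotion", "authenticity")]
  n <- nrow(grid)
  shares <- t(vapply(grid$authenticity,
                     function(a) spec$hrv_shares[[a]], numeric(3)))
  tibble::tibble(
    recording = seq_len(n),
    subject = sprintf("s%03d", grid$subject_i),
    emotion = grid$emotion,
    authenticity = grid$authenticity,
    amp_multiplier = mult[grid$subject_i],
    onset_s = spec$onset_s,
    vlf_share = shares[, 1L], lf_share = shares[, 2L], hf_share = shares[, 3L],
    stream_seed = .derive_seed(spec$seed, seq_len(n), 1L),
    rr_seed = .derive_seed(spec$seed, seq_len(n), 2L)
  )
}

# mix a base seed with a counter so that different base seeds give unrelated
# per-recording seeds (multiplicative congruential step, modulus 2^31 - 1)
.derive_seed <- function(base, counter, tag) {
  m <- 2147483647
  x <- (as.double(base %% m) * 48271 + counter * 16807 + tag * 69621) %% m
  as.integer(x)
}

# regenerate the stream for one manifest row
.stream_for_row <- function(spec, row) {
  generate_stream(
    spec$profiles[[row$emotion]][[row$authenticity]],
    fps = spec$fps, duration_s = spec$duration_s, onset_s = spec$onset_s,
    subject = row$subject, authenticity = row$authenticity,
    amp_multiplier = row$amp_multiplier, seed = row$stream_seed)
}

.rr_for_row <- function(spec, row) {
  generate_rr(c(row$vlf_share, row$lf_share, row$hf_share),
              duration_s = spec$duration_s,
              mod_sd_ms = spec$hrv_mod_sd_ms[[row$authenticity]],
              subject = row$subject, condition = row$authenticity,
              seed = row$rr_seed)
}

#' Generate a full synthetic cohort
#'
#' Materialises every recording of the design: landmark streams and RR
#' series for `n_subjects` x emotions x {real, fake}. For large designs
#' (the default is 320 recordings of 210 s) prefer [cohort_features()] /
#' [cohort_hrv()], which analyse recordings one at a time without holding
#' the streams.
#'
#' @param spec A [cohort_spec()].
#' @return A `cohort`: list with `spec`, `manifest`, `streams` (list of
#'   `landmark_stream`) and `rr` (list of `rr_series`), both ordered as the
#'   manifest.
#' @export
generate_cohort <- function(spec) {
  manifest <- cohort_manifest(spec)
  streams <- vector("list", nrow(manifest))
  rrs <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    streams[[i]] <- .stream_for_row(spec, row)
    rrs[[i]] <- .rr_for_row(spec, row)
  }
  structure(list(spec = spec, manifest = manifest, streams = streams,
                 rr = rrs),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d recordings (%d subjects, %d emotions)\n",
              nrow(x$manifest), x$spec$n_subjects, length(x$spec$emotions)))
  invisible(x)
}

#' Feature table for a whole cohort
#'
#' Runs [feature_table()] on every recording of the design, regenerating
#' each stream from its manifest seed and discarding it after analysis, so
#' memory stays flat for arbitrarily large cohorts.
#'
#' @param spec A [cohort_spec()] or a materialised `cohort`.
#' @param ... Passed to [feature_table()] (`window_s` defaults to the spec's).
#' @return Tibble of bound per-recording feature tables.
#' @export
cohort_features <- function(spec, ...) {
  if (inherits(spec, "cohort")) {
    cohort <- spec
    spec <- cohort$spec
    streams <- cohort$streams
    manifest <- cohort$manifest
  } else {
    stopifnot(inherits(spec, "cohort_spec"))
    streams <- NULL
    manifest <- cohort_manifest(spec)
  }
  args <- list(...)
  if (is.null(args$window_s)) args$window_s <- spec$window_s
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    s <- if (is.null(streams)) .stream_for_row(spec, manifest[i, ]) else
      streams[[i]]
    rows[[i]] <- do.call(feature_table, c(list(s), args))
  }
  dplyr::bind_rows(rows)
}

#' HRV results for a whole cohort
#'
#' [hrv_band_powers()] per recording, regenerated from the manifest seeds.
#'
#' @param spec A [cohort_spec()] or a materialised `cohort`.
#' @param ... Passed to [hrv_band_powers()].
#' @return Tibble with `subject, emotion, authenticity` plus the six HRV
#'   variables per recording.
#' @export
cohort_hrv <- function(spec, ...) {
  if (inherits(spec, "cohort")) {
    cohort <- spec
    spec <- cohort$spec
    rrs <- cohort$rr
    manifest <- cohort$manifest
  } else {
    stopifnot(inherits(spec, "cohort_spec"))
    rrs <- NULL
    manifest <- cohort_manifest(spec)
  }
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    rr <- if (is.null(rrs)) .rr_for_row(spec, manifest[i, ]) else rrs[[i]]
    res <- hrv_band_powers(rr, ...)
    rows[[i]] <- tibble::add_column(res,
      subject = manifest$subject[i], emotion = manifest$emotion[i],
      authenticity = manifest$authenticity[i], .before = 1L)
  }
  dplyr::bind_rows(rows)
}

#' Null profiles: real and fake conditions identical
#'
#' A convenience for type-I error calibration: both conditions use the same
#' expression profile, so any detected difference is a false positive. The
#' default null profile has an onset ramp but no programmed tremor
#' (`vib_amplitude = 0`): a deterministic vibration shared by both
#' conditions would make the spectral-peak feature constant, its paired
#' differences identically zero, and its null rejection rate trivially 0
#' rather than the nominal level; with noise-driven peaks every feature has
#' a non-degenerate null distribution and the t-test calibration is
#' meaningful.
#'
#' @param emotions Emotions to include (default `"happiness"`).
#' @param profile Profile used for both conditions (default: amplitude 6,
#'   no tremor).
#' @return Named list usable as `profiles` in [cohort_spec()].
#' @export
null_profiles <- function(emotions = "happiness", profile = NULL) {
  out <- lapply(emotions, function(em) {
    p <- if (is.null(profile)) {
      expression_profile(em, amplitude = 6, vib_amplitude = 0, vib_freq = 8)
    } else {
      profile
    }
    p$emotion <- em
    list(real = p, fake = p)
  })
  stats::setNames(out, emotions)
}
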