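# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately use naive loops, not the package's code paths.

# componentwise mean of three points by explicit accumulation
oracle_centroid <- function(p1, p2, p3) {
  sx <- 0; sy <- 0
  for (p in list(p1, p2, p3)) {
    sx <- sx + p[1]
    sy <- sy + p[2]
  }
  c(sx / 3, sy / 3)
}

# pairwise previous-minus-current differences by loop
oracle_deltas <- function(pos) {
  n <- nrow(pos)
  out <- matrix(NA_real_, n - 1, 3)
  for (i in 2:n) {
    dx <- pos[i - 1, 1] - pos[i, 1]
    dy <- pos[i - 1, 2] - pos[i, 2]
    out[i - 1, ] <- c(dx, dy, sqrt(dx^2 + dy^2))
  }
  out
}

# two-pass mean and population SD
oracle_mean_sd <- function(v) {
  n <- length(v)
  m <- 0
  for (x in v) m <- m + x / n
  s2 <- 0
  for (x in v) s2 <- s2 + (x - m)^2 / n
  c(mean = m, sd = sqrt(s2))
}

# direct O(n^2) DFT magnitude at bin k (0-based)
oracle_dft_mag <- function(x, k) {
  n <- length(x)
  re <- 0; im <- 0
  for (j in 0:(n - 1)) {
    re <- re + x[j + 1] * cos(-2 * pi * k * j / n)
    im <- im + x[j + 1] * sin(-2 * pi * k * j / n)
  }
  sqrt(re^2 + im^2)
}

# argmax-by-scan dominant frequency within [lo, hi], ties to lower frequency
oracle_dominant_freq <- function(v, fps, lo = 2, hi = fps / 2) {
  x <- v - mean(v)
  n <- length(x)
  best_f <- NA_real_
  best_m <- -Inf
  for (k in 1:floor(n / 2)) {
    f <- k * fps / n
    if (f < lo || f > hi) next
    m <- oracle_dft_mag(x, k)
    if (m > best_m + 1e-12) {
      best_m <- m
      best_f <- f
    }
  }
  best_f
}

# first index strictly above threshold by linear scan
oracle_first_crossing <- function(v, thr) {
  for (i in seq_along(v)) if (v[i] > thr) return(i)
  NA_integer_
}

# a landmark stream with all frames equal to the template (plus optional
# deterministic offsets), bypassing the generator
constant_stream <- function(n_frames = 60, fps = 30, offset = c(0, 0), ...) {
  base <- neutral_face_template()
  row <- as.vector(t(base + matrix(offset, 68, 2, byrow = TRUE)))
  landmark_stream(matrix(row, n_frames, 136, byrow = TRUE), fps = fps, ...)
}

# a small feature table with programmable condition effects, built directly
# (no streams) for exercising the statistics layer quickly. `effect` is added
# to the real condition's mean_delta; `effect_aus` restricts it to those AUs.
make_feature_fixture <- function(n_subjects = 12,
                                 emotions = c("happiness", "contentment",
                                              "anger", "sadness"),
                                 effect = 0, effect_aus = NULL,
                                 peak_effect = 0, sd_noise = 0.1,
                                 seed = 1) {
  set.seed(seed)
  defs <- au_definitions()
  grid <- expand.grid(
    subject = sprintf("s%02d", seq_len(n_subjects)),
    emotion = emotions,
    authenticity = c("real", "fake"),
    au = defs$au,
    section = c("t+0.5", "t+1", "t+4"),
    stringsAsFactors = FALSE)
  grid$side <- defs$side[match(grid$au, defs$au)]
  n <- nrow(grid)
  base <- 1 + 0.2 * as.integer(factor(grid$section))
  eff <- ifelse(grid$authenticity == "real" &
                  (is.null(effect_aus) | grid$au %in% effect_aus), effect, 0)
  tibble::tibble(
    subject = grid$subject, emotion = grid$emotion,
    authenticity = grid$authenticity, au = grid$au, side = grid$side,
    section = grid$section, onset_frame = 450L, n_frames = 30L,
    truncated = FALSE,
    mean_delta = base + eff + rnorm(n, 0, sd_noise),
    sd_delta = 0.5 + 0.5 * eff + rnorm(n, 0, sd_noise),
    dominant_peak_hz = 8 + ifelse(grid$authenticity == "real", peak_effect, 0) +
      rnorm(n, 0, sd_noise))
}
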