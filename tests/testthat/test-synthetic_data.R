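test_that("the neutral template is a valid 68-point face", {
  tpl <- neutral_face_template()
  expect_equal(dim(tpl), c(68L, 2L))
  expect_true(all(is.finite(tpl)))
  expect_true(all(tpl[, 1] > 0 & tpl[, 1] < 1280))
  expect_true(all(tpl[, 2] > 0 & tpl[, 2] < 980))
  # chin (landmark 8) below the brows (landmarks 17-26)
  expect_gt(tpl[9, 2], max(tpl[18:27, 2]))
})

test_that("expression profiles validate their parameters", {
  expect_error(expression_profile("happiness", amplitude = -1), "non-negative")
  expect_error(expression_profile("happiness", vib_freq = 0), "vib_freq")
  expect_error(expression_profile("happiness", vib_freq = 30), "vib_freq")
  expect_error(expression_profile("happiness", ramp_s = 0), "ramp_s")
  expect_error(expression_profile("anger", amplitude = c(bad = 1)), "named")
  per_au <- stats::setNames(1:11, au_definitions()$au)
  p2 <- expression_profile("anger", amplitude = per_au)
  expect_equal(unname(p2$amplitude["AU23_R"]), 11)
})

test_that("zero-amplitude zero-noise profiles give a constant stream", {
  p <- expression_profile("happiness", amplitude = 0, vib_amplitude = 0,
                          vib_freq = 5, noise_sd = 0)
  s <- generate_stream(p, duration_s = 5, onset_s = 2, seed = 1)
  expect_equal(max(s$coords) - max(s$coords[1, ]), 0)
  expect_true(all(abs(sweep(s$coords, 2, s$coords[1, ])) < 1e-12))
})

test_that("streams are deterministic under a fixed seed", {
  p <- default_profiles()$anger$fake
  s1 <- generate_stream(p, duration_s = 10, onset_s = 6, seed = 99)
  s2 <- generate_stream(p, duration_s = 10, onset_s = 6, seed = 99)
  expect_identical(s1$coords, s2$coords)
  s3 <- generate_stream(p, duration_s = 10, onset_s = 6, seed = 100)
  expect_false(identical(s3$coords, s1$coords))
})

test_that("programmed onset and vibration are recovered by the pipeline", {
  p <- expression_profile("happiness", amplitude = 7, vib_amplitude = 1.5,
                          vib_freq = 8)
  s <- generate_stream(p, seed = 17)  # default 210 s, onset at 195 s
  gt <- attr(s, "ground_truth")
  ft <- feature_table(s)
  expect_lt(abs(ft$onset_frame[1] - gt$onset_frame) / 30, 0.5)
  peaks <- ft$dominant_peak_hz[ft$section == "t+4"]
  expect_true(all(abs(peaks - 8) <= 30 / 119 + 1e-9))
})

test_that("left-side amplitudes carry the asymmetry multiplier", {
  p <- expression_profile("anger", amplitude = 6, vib_amplitude = 0,
                          vib_freq = 5, asymmetry = 2, noise_sd = 0)
  s <- generate_stream(p, duration_s = 8, onset_s = 4, seed = 3)
  trajs <- extract_au_trajectories(s)
  excursion <- function(tr) {
    d <- sweep(tr$positions, 2, tr$positions[1, ])
    max(sqrt(rowSums(d^2)))
  }
  # paired AUs: left excursion should be ~2x the right's
  expect_equal(excursion(trajs$AU12_L) / excursion(trajs$AU12_R), 2,
               tolerance = 0.05)
  expect_equal(excursion(trajs$AU5_L) / excursion(trajs$AU5_R), 2,
               tolerance = 0.05)
})

test_that("generate_rr honours programmed band shares", {
  hf_only <- hrv_band_powers(generate_rr(c(0, 0, 1), duration_s = 300,
                                         seed = 7))
  expect_gt(hf_only$hf_pct, 90)

  even <- hrv_band_powers(generate_rr(c(1, 1, 1) / 3, duration_s = 600,
                                      noise_sd_ms = 0, seed = 8))
  expect_equal(even$vlf_pct, 100 / 3, tolerance = 5 / 33.3)
  expect_equal(even$lf_pct, 100 / 3, tolerance = 5 / 33.3)
  expect_equal(even$hf_pct, 100 / 3, tolerance = 5 / 33.3)

  still <- generate_rr(c(0.2, 0.3, 0.5), duration_s = 120, mod_sd_ms = 0,
                       noise_sd_ms = 0, seed = 9)
  expect_warning(res <- hrv_band_powers(still), "zero")
  expect_true(is.na(res$hf_pct))

  expect_error(generate_rr(c(0.5, 0.5, 0.5)), "summing to 1")
})

test_that("the default cohort design has 320 recordings", {
  spec <- cohort_spec()
  m <- cohort_manifest(spec)
  expect_equal(nrow(m), 320L)
  expect_equal(length(unique(m$subject)), 40L)
  expect_equal(nrow(unique(m[, c("emotion", "authenticity")])), 8L)
})

test_that("manifests are reproducible and recordings independently seeded", {
  spec <- cohort_spec(n_subjects = 5, seed = 77)
  m1 <- cohort_manifest(spec)
  m2 <- cohort_manifest(spec)
  expect_identical(m1, m2)
  expect_equal(anyDuplicated(m1$stream_seed), 0L)
  # subject multiplier shared within a subject, positive
  mult <- tapply(m1$amp_multiplier, m1$subject, unique)
  expect_true(all(lengths(mult) == 1L))
  expect_true(all(unlist(mult) > 0))
})

test_that("a materialised cohort matches the lazy per-recording analysis", {
  spec <- cohort_spec(n_subjects = 2, emotions = "happiness",
                      duration_s = 70, window_s = 30, onset_s = 55, seed = 5)
  cohort <- generate_cohort(spec)
  expect_length(cohort$streams, 4L)
  expect_length(cohort$rr, 4L)
  lazy <- cohort_features(spec)
  eager <- cohort_features(cohort)
  expect_identical(lazy, eager)
  lazy_h <- cohort_hrv(spec)
  eager_h <- cohort_hrv(cohort)
  expect_identical(lazy_h, eager_h)
})

test_that("ECG generation places Gaussian R waves at the requested times", {
  peaks <- c(0.5, 1.2, 2.2, 3.4)
  ecg <- generate_ecg(peaks, fs = 500, noise_sd = 0, seed = 2)
  t <- seq(0, attr(ecg, "peak_times_s")[4] + 0.5, by = 1 / 500)
  for (tp in peaks) {
    i <- which.min(abs(t - tp))
    expect_gt(ecg[i], 0.9)
  }
})
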