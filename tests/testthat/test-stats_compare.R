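test_that("star coding is a pure strict-inequality mapping", {
  expect_equal(significance_stars(c(0.0005, 0.005, 0.04, 0.05, 0.2, NA)),
               c("***", "**", "*", "ns", "ns", NA))
  expect_equal(significance_stars(c(0.001, 0.01)), c("**", "*"))
})

test_that("compare_cell handles identical, degenerate and small samples", {
  x <- c(1, 2, 3, 4, 5)
  same <- compare_cell(x, x)
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$stars, "ns")
  expect_equal(same$direction, "none")

  deg <- compare_cell(x + 2, x)  # constant non-zero difference
  expect_false(deg$computable)
  expect_true(is.na(deg$p_value))

  tiny <- compare_cell(c(1, 2), c(3, 4))
  expect_false(tiny$computable)

  na_mix <- compare_cell(c(1, NA, 3, 4, 5), c(2, 3, NA, 5, 7))
  expect_equal(na_mix$n, 3L)
})

test_that("compare_cell matches t.test and directions follow the mean sign", {
  set.seed(51)
  for (i in 1:20) {
    a <- rnorm(15, mean = runif(1, -1, 1))
    b <- rnorm(15)
    cell <- compare_cell(a, b)
    tt <- t.test(a, b, paired = TRUE)
    expect_equal(cell$t_stat, unname(tt$statistic))
    expect_equal(cell$p_value, tt$p.value)
    expect_equal(cell$direction,
                 if (mean(a) > mean(b)) "real>fake" else "fake>real")
    cell_u <- compare_cell(a, b, paired = FALSE)
    expect_equal(cell_u$p_value, t.test(a, b)$p.value)
  }
})

test_that("the paired test has high power at the design effect size", {
  # n = 40 pairs, means 1 vs 1.8, unit variances, correlation 0.5
  set.seed(52)
  reps <- 500
  hits <- 0
  for (i in seq_len(reps)) {
    z <- rnorm(40)
    real <- 1.8 + sqrt(0.5) * z + sqrt(0.5) * rnorm(40)
    fake <- 1.0 + sqrt(0.5) * z + sqrt(0.5) * rnorm(40)
    if (compare_cell(real, fake)$p_value < 0.05) hits <- hits + 1
  }
  expect_gt(hits / reps, 0.9)
})

test_that("comparison grid has 99 cells per emotion and 396 in total", {
  feats <- make_feature_fixture(n_subjects = 8, effect = 0.5, seed = 2)
  cells <- comparison_grid(feats)
  expect_equal(nrow(cells), 396L)
  expect_equal(as.integer(table(cells$emotion)), rep(99L, 4))
  expect_setequal(unique(cells$section), c("t+0.5", "t+1", "t+4"))
  expect_setequal(unique(cells$feature),
                  c("mean_delta", "sd_delta", "dominant_peak_hz"))
})

test_that("an emotion lacking one condition is skipped with a warning", {
  feats <- make_feature_fixture(n_subjects = 6, emotions = c("happiness",
                                                             "anger"))
  feats <- feats[!(feats$emotion == "anger" & feats$authenticity == "fake"), ]
  expect_warning(cells <- comparison_grid(feats), "anger")
  expect_setequal(unique(cells$emotion), "happiness")
})

test_that("programmed left-side effects light up left-side cells", {
  left_aus <- au_definitions()$au[au_definitions()$side == "left"]
  feats <- make_feature_fixture(n_subjects = 20, emotions = "sadness",
                                effect = 0.8, effect_aus = left_aus,
                                seed = 3)
  cells <- comparison_grid(feats)
  md <- cells[cells$feature == "mean_delta", ]
  expect_true(all(md$stars[md$side == "left"] == "***"))
  expect_true(mean(md$stars[md$side != "left"] == "ns") > 0.8)
})

test_that("collapsed comparison pools sections and AUs per subject", {
  feats <- make_feature_fixture(n_subjects = 10, effect = 0.6,
                                peak_effect = -1, seed = 4)
  cc <- collapsed_comparison(feats)
  expect_equal(nrow(cc), 12L)  # 4 emotions x 3 features
  md <- cc[cc$feature == "mean_delta", ]
  expect_true(all(md$direction == "real>fake"))
  pk <- cc[cc$feature == "dominant_peak_hz", ]
  expect_true(all(pk$direction == "fake>real"))

  null_feats <- make_feature_fixture(n_subjects = 10, effect = 0)
  same <- null_feats
  same$mean_delta <- 1  # identical conditions
  cc0 <- collapsed_comparison(same)
  expect_true(all(cc0$direction[cc0$feature == "mean_delta"] == "none"))
})

test_that("face grid and JSON report carry one slot per AU", {
  feats <- make_feature_fixture(n_subjects = 8, emotions = "happiness",
                                effect = 0.5)
  cells <- comparison_grid(feats)
  grid <- face_grid(cells)
  expect_setequal(unique(grid$au), au_definitions()$au)
  path <- withr::local_tempfile(fileext = ".json")
  write_face_grid_json(cells, path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  expect_length(obj, 1L)
  expect_equal(obj[[1]]$emotion, "happiness")
  expect_length(obj[[1]]$slots, 11L)
  slot <- obj[[1]]$slots[[1]]
  expect_true(all(c("au", "side", "cells") %in% names(slot)))
  expect_length(slot$cells, 9L)  # 3 features x 3 sections
  p <- plot_face_grid(cells)
  expect_s3_class(p, "ggplot")
})

test_that("factor regression recovers additive factor structure", {
  set.seed(53)
  defs <- au_definitions()
  grid <- expand.grid(subject = sprintf("s%02d", 1:15),
                      authenticity = c("real", "fake"),
                      au = defs$au,
                      section = c("t+0.5", "t+1", "t+4"),
                      stringsAsFactors = FALSE)
  grid$side <- defs$side[match(grid$au, defs$au)]
  grid$emotion <- "happiness"
  sec_eff <- c("t+0.5" = 0, "t+1" = 0.8, "t+4" = 1.6)
  side_eff <- c(left = 0.4, middle = 0, right = 0)
  grid$mean_delta <- 1 + sec_eff[grid$section] +
    0.6 * (grid$authenticity == "real") + side_eff[grid$side] +
    rnorm(nrow(grid), 0, 0.15)
  grid$sd_delta <- grid$dominant_peak_hz <- 1
  grid$truncated <- FALSE
  fr <- factor_regression(tibble::as_tibble(grid), "happiness")
  expect_gt(fr$r_squared, 0.9)
  expect_true(all(fr$factors$p_value < 0.05))
  expect_false(fr$degenerate)
  expect_output(print(fr), "R-squared")
})

test_that("a null authenticity factor stays non-significant", {
  set.seed(54)
  defs <- au_definitions()
  hits <- 0
  reps <- 40
  for (r in seq_len(reps)) {
    grid <- expand.grid(subject = sprintf("s%02d", 1:12),
                        authenticity = c("real", "fake"),
                        au = defs$au,
                        section = c("t+0.5", "t+1", "t+4"),
                        stringsAsFactors = FALSE)
    grid$side <- defs$side[match(grid$au, defs$au)]
    grid$emotion <- "anger"
    grid$mean_delta <- 1 + 0.5 * (grid$section == "t+4") +
      rnorm(nrow(grid), 0, 0.2)
    grid$truncated <- FALSE
    grid$sd_delta <- grid$dominant_peak_hz <- 1
    fr <- factor_regression(tibble::as_tibble(grid), "anger")
    p_auth <- fr$factors$p_value[fr$factors$factor == "authenticity"]
    if (p_auth > 0.05) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("degenerate designs are reported by factor name", {
  feats <- make_feature_fixture(n_subjects = 5, emotions = "happiness")
  only_real <- feats[feats$authenticity == "real", ]
  expect_error(factor_regression(only_real, "happiness"), "authenticity")

  const <- feats
  const$mean_delta <- 2
  fr <- factor_regression(const, "happiness")
  expect_true(fr$degenerate)
  expect_equal(fr$r_squared, 0)
})

test_that("hrv_comparison confines significance to the differing variables", {
  set.seed(55)
  n <- 30
  base <- tibble::tibble(
    subject = rep(sprintf("s%02d", 1:n), 2),
    authenticity = rep(c("real", "fake"), each = n))
  for (v in c("vlf", "lf", "vlf_pct", "lf_pct")) {
    base[[v]] <- rep(rnorm(n, 100, 10), 2)  # identical within pair
  }
  base$hf <- rnorm(2 * n, 100, 10)
  base$hf_pct <- rnorm(2 * n, 30, 3)
  base$hf[base$authenticity == "fake"] <- base$hf[base$authenticity == "fake"] + 30
  base$hf_pct[base$authenticity == "fake"] <-
    base$hf_pct[base$authenticity == "fake"] + 15
  res <- hrv_comparison(base)
  expect_equal(nrow(res), 6L)
  hf_rows <- res$variable %in% c("hf", "hf_pct")
  expect_true(all(res$p_value[hf_rows] < 0.01))
  expect_true(all(res$direction[hf_rows] == "fake>real"))
  expect_true(all(res$stars[!hf_rows] == "ns"))

  ident <- base
  for (v in c("vlf", "lf", "hf", "vlf_pct", "lf_pct", "hf_pct")) {
    ident[[v]] <- rep(rnorm(n, 100, 10), 2)  # identical conditions
  }
  res0 <- hrv_comparison(ident)
  expect_true(all(res0$direction == "none"))
})

test_that("BH adjustment is available but off by default", {
  feats <- make_feature_fixture(n_subjects = 8, effect = 0.3, seed = 6)
  cells <- comparison_grid(feats)
  expect_false("p_adjusted" %in% names(cells))
  adj <- p_adjust_grid(cells)
  expect_true(all(adj$p_adjusted >= adj$p_value, na.rm = TRUE))
})
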