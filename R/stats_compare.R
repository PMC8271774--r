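#' Three-level significance stars
#'
#' `p < 0.001` gives `"***"`, `p < 0.01` gives `"**"`, `p < 0.05` gives
#' `"*"`, anything else (including exactly 0.05) is `"ns"`. No
#' multiple-testing correction is applied here; see [p_adjust_grid()].
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes (`NA` stays `NA`).
#' @export
significance_stars <- function(p) {
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- ifelse(p[ok] < 0.001, "***",
             ifelse(p[ok] < 0.01, "**",
             ifelse(p[ok] < 0.05, "*", "ns")))
  out
}

#' Compare one feature between real and fake conditions
#'
#' Paired t-test by default (the design is within-subject: every participant
#' provides both conditions); two-sided p-value. Direction follows the sign
#' of the mean difference. Pairs with a missing value in either condition are
#' dropped. Zero-variance non-zero paired differences are degenerate (the t
#' statistic is unbounded) and reported as not computable; identical samples
#' give `t = 0`, `p = 1`.
#'
#' @param real,fake Numeric samples; when `paired`, matched element-wise.
#' @param paired Paired test (default `TRUE`).
#' @param min_n Minimum observations (pairs) required (default 3).
#' @return One-row tibble: `n, t_stat, p_value, mean_real, mean_fake,
#'   mean_diff, direction, stars, computable`.
#' @export
compare_cell <- function(real, fake, paired = TRUE, min_n = 3L) {
  not_computable <- function(n) tibble::tibble(
    n = n, t_stat = NA_real_, p_value = NA_real_,
    mean_real = NA_real_, mean_fake = NA_real_, mean_diff = NA_real_,
    direction = "none", stars = NA_character_, computable = FALSE)
  if (paired) {
    if (length(real) != length(fake)) {
      stop("paired comparison requires equal-length samples", call. = FALSE)
    }
    ok <- !is.na(real) & !is.na(fake)
    real <- real[ok]
    fake <- fake[ok]
    n <- length(real)
    if (n < min_n) return(not_computable(n))
    d <- real - fake
    if (stats::sd(d) == 0) {
      if (all(d == 0)) {
        t_stat <- 0; p <- 1
      } else {
        return(not_computable(n))           # constant non-zero difference
      }
    } else {
      tt <- stats::t.test(real, fake, paired = TRUE)
      t_stat <- unname(tt$statistic); p <- tt$p.value
    }
  } else {
    real <- real[!is.na(real)]
    fake <- fake[!is.na(fake)]
    n <- min(length(real), length(fake))
    if (n < min_n) return(not_computable(n))
    if (stats::sd(real) == 0 && stats::sd(fake) == 0) {
      if (mean(real) == mean(fake)) {
        t_stat <- 0; p <- 1
      } else {
        return(not_computable(n))
      }
    } else {
      tt <- stats::t.test(real, fake)
      t_stat <- unname(tt$statistic); p <- tt$p.value
    }
  }
  md <- mean(real) - mean(fake)
  tibble::tibble(
    n = n, t_stat = t_stat, p_value = p,
    mean_real = mean(real), mean_fake = mean(fake), mean_diff = md,
    direction = if (md > 0) "real>fake" else if (md < 0) "fake>real" else "none",
    stars = significance_stars(p), computable = TRUE)
}

# pivot a feature table to long form, one row per subject x condition x cell
.features_long <- function(features, sections, drop_truncated) {
  long <- tidyr::pivot_longer(
    features,
    cols = c("mean_delta", "sd_delta", "dominant_peak_hz"),
    names_to = "feature", values_to = "value")
  long <- dplyr::filter(long, .data$section %in% sections)
  if (drop_truncated) {
    long <- dplyr::filter(long, !is.na(.data$truncated) & !.data$truncated)
  }
  long
}

#' Per-AU, per-section, per-feature real-vs-fake comparison grid
#'
#' For every emotion present with both conditions: 11 AUs x 3 post-onset
#' sections x 3 features = 99 comparison cells per emotion. Truncated
#' sections are excluded by default; the pre-onset section is not part of
#' the headline comparisons.
#'
#' @param features Feature table covering both conditions (rows from
#'   [feature_table()] bound over recordings).
#' @param paired Paired t-tests, matching conditions by subject (default
#'   `TRUE`).
#' @param sections Sections compared (default the three post-onset sections).
#' @param drop_truncated Exclude truncated sections (default `TRUE`).
#' @return A tibble of comparison cells: `emotion, au, side, section,
#'   feature` plus the [compare_cell()] columns.
#' @export
comparison_grid <- function(features, paired = TRUE,
                            sections = c("t+0.5", "t+1", "t+4"),
                            drop_truncated = TRUE) {
  long <- .features_long(features, sections, drop_truncated)
  for (em in unique(long$emotion)) {
    present <- unique(long$authenticity[long$emotion == em])
    if (!all(c("real", "fake") %in% present)) {
      warning("emotion '", em, "' lacks one condition; skipped", call. = FALSE)
      long <- dplyr::filter(long, .data$emotion != em)
    }
  }
  if (nrow(long) == 0L) stop("no emotion has both conditions", call. = FALSE)
  wide <- tidyr::pivot_wider(
    long,
    id_cols = c("emotion", "au", "side", "section", "feature", "subject"),
    names_from = "authenticity", values_from = "value")
  grouped <- dplyr::group_by(wide, .data$emotion, .data$au, .data$side,
                             .data$section, .data$feature)
  out <- dplyr::reframe(grouped,
                        compare_cell(.data$real, .data$fake, paired = paired))
  tibble::as_tibble(out)
}

#' Optional multiple-testing adjustment of a comparison grid
#'
#' The three-level star report is uncorrected by design; this helper adds
#' Benjamini-Hochberg adjusted p-values and stars for users who want them.
#'
#' @param cells Tibble from [comparison_grid()].
#' @param method Passed to [stats::p.adjust()] (default `"BH"`).
#' @return `cells` with `p_adjusted` and `stars_adjusted` columns.
#' @export
p_adjust_grid <- function(cells, method = "BH") {
  cells$p_adjusted <- stats::p.adjust(cells$p_value, method = method)
  cells$stars_adjusted <- significance_stars(cells$p_adjusted)
  cells
}

#' Face-grid report of a comparison grid
#'
#' The 11-slot face layout used for reporting: one slot per AU, placed on
#' the left, right or middle of a schematic face, listing the significance
#' code of every feature x section cell.
#'
#' @param cells Tibble from [comparison_grid()].
#' @return Tibble `emotion, au, side, feature, section, stars, direction`
#'   ordered by slot.
#' @export
face_grid <- function(cells) {
  dplyr::arrange(
    dplyr::select(cells, "emotion", "au", "side", "feature", "section",
                  "stars", "direction"),
    .data$emotion, .data$side, .data$au, .data$feature, .data$section)
}

#' Write a face-grid report as structured JSON
#' @param cells Tibble from [comparison_grid()] (or [face_grid()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_face_grid_json <- function(cells, path) {
  grid <- face_grid(cells)
  split_em <- split(grid, grid$emotion)
  obj <- lapply(names(split_em), function(em) {
    g <- split_em[[em]]
    slots <- lapply(split(g, g$au), function(a) {
      list(au = a$au[1L], side = a$side[1L],
           cells = lapply(seq_len(nrow(a)), function(i) {
             list(feature = a$feature[i], section = a$section[i],
                  stars = a$stars[i], direction = a$direction[i])
           }))
    })
    list(emotion = em, slots = unname(slots))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Plot a face-grid significance map
#'
#' A tile map per AU slot (facetted by AU, columns ordered left/middle/right)
#' with the star level as fill, echoing the face-layout report figure.
#'
#' @param cells Tibble from [comparison_grid()], ideally one emotion.
#' @return A ggplot object.
#' @export
plot_face_grid <- function(cells) {
  cells$stars <- factor(cells$stars, levels = c("ns", "*", "**", "***"))
  cells$au <- factor(cells$au,
                     levels = unique(cells$au[order(match(cells$side,
                       c("left", "middle", "right")))]))
  ggplot2::ggplot(cells,
                  ggplot2::aes(x = .data$section, y = .data$feature,
                               fill = .data$stars)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::facet_wrap(~ au, nrow = 3) +
    ggplot2::scale_fill_manual(
      values = c(ns = "grey90", `*` = "#fee08b", `**` = "#fc8d59",
                 `***` = "#d73027"),
      drop = FALSE) +
    ggplot2::labs(x = "section", y = "feature", fill = "significance") +
    ggplot2::theme_minimal()
}

#' Collapsed-section condition summary
#'
#' Pools the three post-onset sections and all AUs: per emotion and feature,
#' each subject contributes one mean value per condition, compared with a
#' paired t-test. The per-emotion bar-chart analogue of the per-cell grid.
#'
#' @inheritParams comparison_grid
#' @return Tibble `emotion, feature` plus [compare_cell()] columns.
#' @export
collapsed_comparison <- function(features, paired = TRUE,
                                 sections = c("t+0.5", "t+1", "t+4"),
                                 drop_truncated = TRUE) {
  long <- .features_long(features, sections, drop_truncated)
  per_subj <- dplyr::summarise(
    dplyr::group_by(long, .data$emotion, .data$feature, .data$subject,
                    .data$authenticity),
    value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  wide <- tidyr::pivot_wider(per_subj, names_from = "authenticity",
                             values_from = "value")
  if (!all(c("real", "fake") %in% names(wide))) {
    stop("both conditions are required", call. = FALSE)
  }
  grouped <- dplyr::group_by(wide, .data$emotion, .data$feature)
  tibble::as_tibble(dplyr::reframe(
    grouped, compare_cell(.data$real, .data$fake, paired = paired)))
}

#' Factor regression on average movement
#'
#' Linear model of a feature (default `mean_delta`) on the categorical
#' factors time segment, authenticity and face side (main effects, fitted
#' simultaneously), per emotion. Reports the model R-squared and a per-factor
#' F-test p-value.
#'
#' @param features Feature table covering both conditions.
#' @param emotion Emotion analysed.
#' @param response Feature used as response (default `"mean_delta"`).
#' @param sections Sections included (default the three post-onset sections).
#' @return An object of class `factor_regression`: `emotion`, `response`,
#'   `r_squared`, `factors` (tibble `factor, df, f_value, p_value`),
#'   `coefficients` and the fitted `model`.
#' @export
factor_regression <- function(features, emotion,
                              response = "mean_delta",
                              sections = c("t+0.5", "t+1", "t+4")) {
  df <- dplyr::filter(features, .data$emotion == !!emotion,
                      .data$section %in% sections,
                      !is.na(.data[[response]]))
  if (nrow(df) == 0L) stop("no rows for emotion '", emotion, "'", call. = FALSE)
  factors <- c("section", "authenticity", "side")
  for (f in factors) {
    if (length(unique(df[[f]])) < 2L) {
      stop("factor '", f, "' has fewer than 2 levels; design is degenerate",
           call. = FALSE)
    }
  }
  df$section <- factor(df$section, levels = sections)
  df$authenticity <- factor(df$authenticity, levels = .authenticities)
  df$side <- factor(df$side, levels = c("left", "middle", "right"))
  if (stats::var(df[[response]]) == 0) {
    # constant response: nothing to explain; flag rather than fit
    return(structure(list(emotion = emotion, response = response,
                          r_squared = 0,
                          factors = tibble::tibble(factor = factors,
                                                   df = NA_integer_,
                                                   f_value = NA_real_,
                                                   p_value = NA_real_),
                          coefficients = NULL, model = NULL,
                          degenerate = TRUE),
                     class = "factor_regression"))
  }
  fit <- stats::lm(stats::reformulate(factors, response), data = df)
  dr <- stats::drop1(fit, test = "F")
  fac_tbl <- tibble::tibble(
    factor = rownames(dr)[-1L],
    df = dr$Df[-1L],
    f_value = dr$`F value`[-1L],
    p_value = dr$`Pr(>F)`[-1L])
  structure(list(emotion = emotion, response = response,
                 r_squared = summary(fit)$r.squared,
                 factors = fac_tbl,
                 coefficients = stats::coef(fit),
                 model = fit,
                 degenerate = FALSE),
            class = "factor_regression")
}

#' @export
print.factor_regression <- function(x, ...) {
  cat(sprintf("<factor_regression> %s ~ section + authenticity + side (%s)\n",
              x$response, x$emotion))
  cat(sprintf("  R-squared = %.3f\n", x$r_squared))
  for (i in seq_len(nrow(x$factors))) {
    cat(sprintf("  %-13s F = %8.2f  p = %.3g %s\n",
                x$factors$factor[i], x$factors$f_value[i],
                x$factors$p_value[i],
                significance_stars(x$factors$p_value[i])))
  }
  invisible(x)
}

#' Real-vs-fake comparison of HRV variables
#'
#' Paired tests on the six frequency-domain variables (VLF, LF, HF absolute
#' powers and percentages). Subjects contributing several recordings per
#' condition (e.g. one per emotion) are first averaged within subject and
#' condition.
#'
#' @param hrv Tibble with columns `subject`, `authenticity` and the six
#'   variables `vlf, lf, hf, vlf_pct, lf_pct, hf_pct` (one row per
#'   recording), e.g. from [cohort_hrv()].
#' @param paired Paired tests (default `TRUE`).
#' @return Tibble with one row per variable plus [compare_cell()] columns.
#' @export
hrv_comparison <- function(hrv, paired = TRUE) {
  vars <- c("vlf", "lf", "hf", "vlf_pct", "lf_pct", "hf_pct")
  stopifnot(all(c("subject", "authenticity", vars) %in% names(hrv)))
  long <- tidyr::pivot_longer(hrv[, c("subject", "authenticity", vars)],
                              cols = dplyr::all_of(vars),
                              names_to = "variable", values_to = "value")
  per_subj <- dplyr::summarise(
    dplyr::group_by(long, .data$variable, .data$subject, .data$authenticity),
    value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  wide <- tidyr::pivot_wider(per_subj, names_from = "authenticity",
                             values_from = "value")
  if (!all(c("real", "fake") %in% names(wide))) {
    stop("both conditions are required", call. = FALSE)
  }
  grouped <- dplyr::group_by(wide, .data$variable)
  out <- tibble::as_tibble(dplyr::reframe(
    grouped, compare_cell(.data$real, .data$fake, paired = paired)))
  out$variable <- factor(out$variable, levels = vars)
  dplyr::arrange(out, .data$variable)
}
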