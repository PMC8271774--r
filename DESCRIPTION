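Package: micromov
Title: Facial Micromovement Analysis of Emotion Authenticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether a cued facial expression is genuine or
    posed from the kinematics of facial micromovements. Maps 68-point facial
    landmark streams to eleven action-unit (AU) centroid trajectories, detects
    expression onset with a min-max midrange threshold, extracts frame-delta
    features (mean and standard deviation of per-frame displacement, dominant
    spectral peak frequency of the delta series) over pre-onset and 0.5/1/4-s
    post-onset sections, and compares real versus fake conditions per AU,
    emotion and section with paired t-tests, collapsed-section summaries and
    factor regressions. A parallel frequency-domain heart-rate-variability
    module (VLF/LF/HF band powers from RR-interval tachograms, with a sliding
    window) cross-validates the facial findings. A synthetic-data generator
    produces landmark streams, RR series and full cohorts with programmable
    ground truth (onset time, vibration frequency, band-power shares, effect
    directions) for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    rlang,
    signal,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
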