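---
title: "Methods: facial micromovement analysis of emotion authenticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: facial micromovement analysis of emotion authenticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micromov)
```

## The problem and the measurement model

People routinely pose expressions they do not feel. Genuine and posed
expressions differ in the *micromovements* of the face: involuntary,
sub-second movements with vibration periods of roughly 0.04–0.5 s
(2–25 Hz), superimposed on the slower macroexpression (≤ 4 s). `micromov`
quantifies these kinematics from 68-point facial landmark streams (30 fps
webcam video is the intended source; the package consumes the landmark
coordinates, not video) and tests whether they separate *real* from *fake*
expressions of four emotions — happiness, contentment, anger, sadness — in a
within-subject design. A parallel heart-rate-variability (HRV) module
cross-validates the facial findings with an autonomic measure.

The pipeline has five stages:

1. **AU geometry.** Eleven action units (AUs) are operationalised as the
   centroid of three landmarks each,
   \(P = \left(\frac{x_1+x_2+x_3}{3}, \frac{y_1+y_2+y_3}{3}\right)\).
   The triples (see `au_definitions()`) cover the brow (AU4), upper lids
   (AU5), cheeks (AU6), lip corners (AU12, AU15) and lips (AU23), with
   left/right variants for all but the brow. Landmark indices are 0-based
   labels in the standard 68-point annotation scheme, the convention of the
   landmark models that produce such streams; the largest index used is 63.
   Only the trailing 30 s of a recording is analysed
   (`extract_analysis_window()`): earlier frames are treated as stimulus
   "sink-in" time.

2. **Onset segmentation.** The expression onset \(t\) is the first frame at
   which an AU's movement signal strictly exceeds the min-max midrange
   threshold \((\max + \min)/2\). The thresholded scalar is not prescribed
   by the measurement model itself, so the package defines it: Euclidean
   displacement of the AU centroid from a neutral baseline (the mean
   centroid over the first second of the analysis window), optionally
   smoothed with a 5-frame moving average (on by default) to suppress
   single-frame jitter crossings. Displacement from neutral rises
   monotonically through an onset, which makes the midrange crossing well
   defined. Onset is treated as one event per expression: the default is
   the median of per-AU onsets (`global_onset()`); per-AU onsets are
   available with `feature_table(global = FALSE)`. From \(t\), four
   sections are cut: the pre-onset micromovement section \([window
   start, t)\) and three post-onset sections of 0.5 s, 1 s
   (micromovement) and 4 s (macromovement), all starting at \(t\) and
   therefore overlapping (15, 30 and 120 frames at 30 fps). Sections that
   run past the window end are truncated and flagged; flagged sections are
   excluded from the statistics by default.

3. **Feature variables.** Per AU and section, frame-to-frame deltas
   \(x_n = \mathrm{prev}_x - \mathrm{curr}_x\),
   \(y_n = \mathrm{prev}_y - \mathrm{curr}_y\) are reduced to the Euclidean
   magnitude \(\sqrt{x_n^2 + y_n^2}\), and three features are computed:
   the **mean** and **standard deviation** of the magnitude (degree and
   variance of movement, px/frame) and the **dominant peak frequency** (Hz)
   of the mean-removed magnitude series — the vibration level, from the
   maximum-magnitude FFT bin.

4. **Statistics.** Per emotion, AU, post-onset section and feature, the
   real and fake conditions are compared with a paired two-sided t-test
   (the design is within-subject; `paired = FALSE` is available), coded at
   three significance levels (\*\*\* p < 0.001, \*\* p < 0.01, \* p < 0.05,
   strict inequalities). `collapsed_comparison()` pools sections and AUs to
   one value per subject and condition. `factor_regression()` fits the
   feature on the categorical factors time segment, authenticity and face
   side. `hrv_comparison()` applies the same paired test to the six HRV
   variables.

5. **HRV.** RR-interval series are laid out at their cumulative beat times
   (tachogram, ms), resampled to 4 Hz by cubic spline, mean-removed and
   Fourier-transformed. Band powers integrate the spectrum over VLF
   0.003–0.04 Hz, LF 0.04–0.15 Hz and HF 0.15–0.4 Hz (half-open bands);
   percentages are taken relative to the three-band sum. A 180-s sliding
   window (default step 10 s) gives a time course.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `window_s` | 30 | s | trailing portion of the recording containing the cued expression |
| `baseline_s` | 1 | s | neutral baseline for the movement signal; must precede the onset |
| `smooth_n` | 5 | frames | jitter suppression before thresholding (~0.17 s at 30 fps) |
| sections | 0.5, 1, 4 | s | micro- and macromovement horizons after onset |
| `band_low` | 2 | Hz | micromovement vibration periods are 0.04–0.5 s; also excludes DC and ramp drift |
| `sd_type` | population | — | a convention must be fixed; sample SD available |
| `resample_hz` | 4 | Hz | tachogram grid; comfortably above 2×HF upper edge |
| `min_frames` (spectral) | 8 | frames | below this, a peak estimate is unstable; reported absent instead |

## Numerical choices

* **Spectral peak.** DC is removed before the transform; no window function
  by default (sections are short; a Hann option exists). Ties in the peak
  search break toward the lower frequency so output is deterministic. The
  peak is only reported within `[band_low, fps/2]`.
* **Onset.** The first *strictly* greater crossing is used, which makes the
  constant (degenerate) signal unambiguous: it has no onset and is reported
  as such. A global onset is the rounded median of per-AU onsets.
* **Degenerate statistics.** Zero-variance paired differences are reported
  as not computable rather than p = 0 (identical samples give t = 0,
  p = 1). A constant regression response is flagged degenerate with
  R² = 0 rather than fitted. No multiple-testing correction is applied, to
  match the three-level star report; `p_adjust_grid()` adds
  Benjamini–Hochberg values for users who want them.
* **Percentage closure.** The "overall power" denominator of the HRV
  percentages is defined as the VLF+LF+HF sum — the only self-contained
  choice — so the three percentages always close to 100.
* **Units.** Coordinates are raw image pixels (y downward); no
  normalisation by inter-ocular distance is applied, since the analysis is
  within-subject and paired. Tachogram and band powers are in ms and ms².

## What the synthetic generator emulates — and what it does not

The measurement model was developed for human recordings that are not
distributed with any public dataset, so the package ships a generator
(`generate_stream()`, `generate_rr()`, `generate_cohort()`) that produces
inputs with *programmable ground truth*: every quantity the pipeline is
supposed to estimate — onset time, vibration frequency, band-power shares,
effect directions — is a generator parameter, and the test suite checks
that the pipeline recovers it.

A synthetic recording is a fixed schematic 68-point face in a 1280 × 980
frame with per-landmark Gaussian jitter (default SD 0.3 px, the scale of
landmark-detector noise on a steady face). At the cue (default 15 s before
the end, i.e. the middle of the analysis window) the landmarks of each AU
move outward along the radial direction from the face centre, following a
logistic ramp (default 1 s, amplitude 4–9 px depending on emotion and
condition), superposed with a tremor. The tremor is modelled as muscle
twitches whose *speed* — the frame-delta magnitude, the very series the
spectral feature analyses — is a raised cosine at the programmed frequency,
with the movement direction alternating at the speed zeros so the position
stays bounded. This choice is deliberate: a bidirectional positional
sinusoid at \(f\) yields a delta-*magnitude* series whose energy folds onto
harmonics of \(f\) (and their aliases) through the rectification
\(|\cdot|\), so its programmed frequency would not be the quantity the
feature estimates. With the twitch-train model the delta magnitude is
spectrally pure at \(f\) and generator truth and feature definition
coincide.

Cohorts follow the study design: 40 subjects × 4 emotions × 2 conditions =
320 recordings of 210 s at 30 fps, with a lognormal subject-level amplitude
multiplier (SD 0.2) shared between the two conditions of a pair. The
default condition profiles encode the qualitative contrast the analysis is
built to detect — more movement in real expressions for every emotion, and
for the low-arousal emotions (contentment, sadness) faster vibration in the
fake condition. Effect sizes are illustrative free parameters, not measured
quantities. RR series are generated with one sinusoid per HRV band at the
band's geometric-centre frequency, amplitudes set to the requested power
shares (defaults: real 45/28/27, fake 25/28/47 with a larger total in the
fake condition), plus white beat-to-beat noise.

The generator does **not** emulate: head pose changes or rigid motion,
landmark-detector failure modes (outliers, identity switches), appearance
or texture, multiple expressions per window, ectopic beats or measurement
artefacts in the RR series. Passing tests therefore demonstrate that the
pipeline measures what it claims on data that satisfy its assumptions; they
do not certify performance on adversarial real-world video.

For type-I calibration the null cohorts use a profile with an onset ramp
but *no* tremor, and identical profiles in both conditions. With a shared
deterministic tremor the spectral-peak feature would be constant, its
paired differences identically zero, and its "rejection rate" trivially
zero — which says nothing about test calibration. With noise-driven peaks
every feature has a non-degenerate null distribution.

## Validation problem sizes

The suite validates elementary operations against brute-force oracles
(naive loops and an O(n²) DFT) on 100 random instances each; vibration
recovery at 4/8/12 Hz within one frequency bin of the 4-s section;
onset recovery within ±0.5 s over 50 seeded streams; HRV share recovery
within ±5 percentage points on a programmed 20/30/50 mixture (600-s
series, where the VLF main lobe fits inside its band); type-I calibration
over 200 null cohorts of 40 subjects at 0.05 ± 0.02, using 9-s recordings
with a 7-s analysis window so that section structure is preserved while the
simulation stays cheap; and direction recovery on a 40-subject cohort with
36-s recordings. Recording lengths in the simulation-heavy checks are
package choices that keep the generator fast; every structural constant
(900-frame window, 15/30/120-frame sections, 320-recording design) is
asserted at full scale.

## Known limitations

* The movement scalar (displacement from a 1-s baseline) and the smoothing
  are package definitions; other operationalisations of "average movement
  of an AU" (frame deltas, smoothed envelopes) would shift detected onsets
  by a few frames.
* The dominant-peak feature is a single argmax: it is sensitive to
  broadband noise when no tremor is present (by design — that is what makes
  the null calibration meaningful) and reports one frequency even when the
  spectrum is multimodal.
* Sections shorter than 8 delta samples report no spectral feature; at
  30 fps the 0.5-s section yields 14 samples and a coarse 2.1-Hz bin width,
  so low-frequency tremor is only coarsely resolved there.
* HRV percentages are closed within VLF+LF+HF; they are not comparable to
  conventions that include total power above 0.4 Hz or below 0.003 Hz.
* On 210-s recordings the VLF band holds barely two cycles of its
  lowest-period content; absolute VLF power is noisy at that length, which
  is why the sliding window is 180 s and why share-recovery checks use
  longer synthetic series.
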