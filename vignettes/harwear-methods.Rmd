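---
title: "Methods: simulating and classifying wearable sensor activity data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying wearable sensor activity data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`harwear` implements a complete activity-recognition pipeline for
smartphone and smartwatch sensor streams: multi-rate ingestion, resampling,
a gravity/gait filter split, two-second window feature generation,
balanced/unbalanced dataset assembly, five-classifier cross-validated
evaluation with optional PCA reduction, and GPS–light fusion for
indoor/outdoor detection. Because no deposited recordings accompany this
kind of protocol study, the package ships a first-class synthetic-data
generator whose defaults define the study conditions everything else is
tested against.

This vignette documents the signal models, the numeric choices, and the
boundaries of what synthetic validation can show.

# The synthetic session generator

`simulate_session()` renders an ordered activity protocol into raw,
irregularly timestamped streams per device.

**Accelerometer.** Each bout contributes a static plus dynamic model:

* the static part is the gravity reaction vector, `9.81` m/s² rotated so
  the device Y axis makes the posture's configured angle with vertical
  (e.g. ~10° for a phone upright in a pants pocket while walking, ~85°
  while seated). An arbitrary azimuth about the vertical axis is drawn per
  bout; it leaves the Y-angle invariant but rotates the magnetic field.
* the dynamic part is a harmonic gait waveform — a fundamental plus two
  harmonics with relative amplitudes 1 / 0.4 / 0.15, normalised to unit
  peak and scaled by the activity's peak dynamic amplitude. The three
  device axes receive it with weights 0.4 / 1.0 / 0.3 (vertical bounce
  dominates). This is the simplest signal with a realistic spectral spread:
  a dominant fundamental inside the gait band, harmonics that exercise the
  band edges.
* white Gaussian noise, SD 0.05 m/s² (phone-grade MEMS).

**Magnetometer and gyroscope.** The magnetometer sees a 50 µT field at 60°
inclination in the device frame plus the gait component at half amplitude;
the gyroscope carries only the gait component (quarter amplitude) plus
noise. No disturbance fields or bias drift are modelled.

**Pressure.** The altitude track integrates each bout's vertical rate —
trapezoidal for elevators (2 s acceleration and deceleration ramps around a
cruise), constant for stairs — and is converted to pressure through the
international barometric formula, `h = 44330 (1 - (p/1013.25)^{1/5.255})`,
plus 0.03 hPa of sensor noise. The standard-atmosphere formula is used
throughout; at sea level 0.12 hPa corresponds to ~1 m, and 1 mmHg to
~11 m. Informal rules of thumb that attach ~8.4 m to "one unit" of
pressure refer to 1 hPa, not 1 mmHg, and are not part of the model.

**Sampling.** Nominal rates are 90 / 25 / 27 / 5 Hz for the phone's
accelerometer, magnetometer, gyroscope and barometer and 15 Hz for the
watch accelerometer, with ±5% uniform timestamp jitter to exercise the
interpolator. Timestamps start at 0 and extend one sample past the protocol
end so the resampled grid covers every annotated segment.

**Watch dropout.** When a bout is sedentary (zero dynamic amplitude and
zero vertical rate — sitting and standing), the watch accelerometer emits
no samples, emulating a power-saving shutdown. Downstream,
`fill_hold_last()` repairs gaps longer than 2 s (one analysis window) by
repeating the last observed value at the nominal rate; shorter gaps are
left to linear interpolation. Two seconds separates plausible timestamp
jitter from genuine power-downs.

**Cohorts.** `simulate_cohort()` perturbs each subject's profiles — gait
frequency ±5%, amplitude ±10%, posture angle ±3° (1 SD) — emulating
between-subject variability while keeping classes separable. The default
protocol is a ten-minute scripted sequence in which walking dominates and
stair/elevator bouts are short, as in a realistic two-building protocol.

**Transition walks.** `simulate_transition_walk()` renders the phone light
stream and GPS fixes for an indoor span followed by an outdoor span.
Defaults: indoor 200 lx, outdoor daylight 10,000 lx (order-of-magnitude
realistic illuminance levels); indoors GPS is invisible (no fixes),
outdoors fixes at 1 Hz carry ~9 visible satellites at ~35 dB-Hz mean SNR.
The walk's bearing is a constant heading with per-fix scatter — a
deliberately structureless choice so that, when both sides are given
identical profiles, no incidental time-locked cue remains and classifiers
fall to chance.

# Resampling and filtering

Inertial streams are linearly interpolated to 100 Hz, pressure and light to
10 Hz; values are never extrapolated beyond the raw span, and GPS fixes are
never interpolated (they are aggregated per window). The filter bank is a
4th-order Butterworth applied forward–backward (zero phase):

* gravity low-pass, cutoff 0.6 Hz — isolates orientation;
* gait band-pass, 0.6–7.5 Hz — the band retaining typical human gait
  periodicity, applied to accelerometer, magnetometer and gyroscope;
* pressure high-pass, cutoff 0.1 Hz — removes weather-scale drift.

Zero-phase filtering was chosen (over a causal implementation) so that
filtered windows stay aligned with the annotation timeline; nothing here
runs in real time, so the non-causality costs nothing. Signals are centred
before filtering (the offset is restored through the exact DC gain) and
padded by odd reflection over roughly two periods of the slowest cutoff,
which keeps edge transients out of the analysed span even for strongly
offset signals such as absolute pressure.

# Windowing and features

Accepted annotated segments are cut into non-overlapping, contiguous 2 s
windows aligned to the segment start; trailing remainders are discarded,
and no window crosses a segment boundary. Non-overlapping windows are the
conservative choice: they keep instances independent for cross-validation.
A window requires every needed sensor slice; windows a device's signals
cannot cover are dropped and counted.

The phone schema has exactly 53 attributes, the watch 17 (accelerometry
only). Definitions:

* **Activity counts** — the classical actigraphy epoch count: rectified
  integral of the band-passed signal per axis. A unit 2 Hz tone over 2 s
  gives `4/π ≈ 1.273`.
* **RMS counts** — RMS of the per-sample vector magnitude over the window.
* **Device angles** — against the device +Y axis (the vertical reference):
  uncorrected is the mean of instantaneous angles of the low-passed vector;
  corrected is the angle of the window's mean gravity vector. Windows whose
  mean field magnitude falls below 10% of nominal (9.81 m/s², 50 µT) have
  the angle flagged missing.
* **Coefficients of variation** — computed on the rectified signal, since
  a band-passed signal's raw mean is ~0 and would make the ratio unstable.
  For a rectified sinusoid the closed form is `sqrt(π²/8 − 1) ≈ 0.483`.
* **Spectral features** — raw periodogram per axis on the 200-sample
  window (0.5 Hz resolution): per-axis max power and its bin frequency
  (DC excluded), the max over axes, and the primary frequency of the bin
  maximising power summed over axes.
* **Step counts** — local maxima above 0.5 × window RMS with ≥0.25 s
  separation (a 4 Hz cadence ceiling, inside the 7.5 Hz band), accepted
  tallest-first.
* **Estimated distance** — detrended double trapezoidal integration per
  axis, then the norm of per-axis peak displacements. This is an
  oscillatory-displacement proxy, not dead reckoning: constant acceleration
  integrates to exactly zero by construction.
* **Altitude features** — the within-window altitude change and
  least-squares slope, from raw (not high-passed) pressure via the
  barometric formula, so absolute differences remain meaningful.

The watch subset keeps counts (×3), vector RMS (×1), peak frequency (×3),
max power (×3), peak power (×1), primary frequency (×1), step count (×3)
and both angle variants (×2) — 17 attributes from the accelerometer alone.

# Geo features and indoor/outdoor detection

Per window: circular-mean bearing (a vector mean, correct across the 0/360
wrap), arithmetic mean speed, altitude, satellite count and SNR; and the
raw-mean, low-passed-mean (0.5 Hz cutoff) and mean-first-difference of lux.
An empty fix list yields satellite count 0 and SNR 0 with the remaining
GPS fields missing — absence encoded as signal, which is precisely the
discriminative indoor cue.

Two processing choices matter at transitions. A doorway is an effectively
instantaneous lux step, so the light stream is resampled *and* low-passed
within each annotated span: letting the interpolator or the smoothing
filter bridge the boundary would manufacture windows containing a mixture
of both environments. Likewise, classifiers that tolerate missing values
natively (trees, naive Bayes) receive the GPS fields' `NA`s untouched;
median imputation is applied only for the perceptron and SVM, which require
complete numeric input. Imputing for naive Bayes would fabricate an
indoor bearing distribution out of outdoor medians.

One further numerical guard: `e1071`'s naive Bayes prediction clips
per-feature densities at 1e-3 by default, which can rank an impossible
class above a diffuse correct one when class variances differ by orders of
magnitude (satellite counts: exactly 0 indoors, ~9 ± 1 outdoors). The
package predicts with a floor of 1e-300 instead, and patches degenerate
within-class parameters (zero variance, or a class that never observes a
feature) to keep every density finite.

# Datasets and evaluation

`build_dataset()` restricts the phone schema to per-sensor column subsets
(accelerometer 21, magnetometer 19, gyroscope 11, pressure 2, fused 53).
`balance_dataset()` subsamples every class without replacement to the
minimum class count — with nine balanced classes each activity can
contribute at most 100/9 ≈ 11.1% of the overall true-positive rate.

Evaluation is stratified 10-fold cross-validation (the natural protocol for
a cohort of this size; instances are windows, folds stratified by class),
aggregating out-of-fold predictions into a confusion matrix. The five
classifiers are realised as: information-gain and Gini `rpart` trees
(`c45`, `cart`), Gaussian naive Bayes (`nb`), a single-hidden-layer
perceptron with hidden size half the feature count (`mlp`,
standardised inputs, weight decay 1e-3), and an RBF-kernel SVM with default
regularisation (`svm`, standardised inputs). Scaling and imputation are fit
on training folds only. PCA (`pca_reduce()`) standardises columns, drops
constant ones, and keeps the smallest component count reaching 95%
cumulative explained variance.

# Problem sizes and determinism

The package's own validation uses: a 10-subject default cohort (~3,000
phone windows) for the end-to-end performance bars; 220 s single-activity
sessions (≥100 windows each) for spectral/angle recovery; 20 permutation
seeds for chance-level calibration; and 5 transition walks (~1,500
windows) for indoor/outdoor detection. All randomness flows through
explicit integer seeds (`withr::with_seed`), so identical seeds give
bit-identical streams, datasets and reports.

# What synthetic validation does and does not show

Passing tests demonstrate that the pipeline is internally correct: filters
meet their gain contracts, features match closed forms, generated ground
truth (gait frequency, posture angle, altitude rate, environment) is
recovered, balancing and evaluation behave as specified, and separable
conditions are separated while degenerate ones fall to chance. They do
*not* demonstrate field performance: the generator has no biomechanical
model (no soft-tissue artefact, no arm-swing coupling for the watch, no
pocket-orientation drift), no magnetic disturbances, no GPS multipath or
urban-canyon effects, and between-subject variability is a mild parameter
jitter rather than true behavioural diversity. Real-data accuracies will be
lower and should be established on real recordings; the synthetic bars
(e.g. trees ≥85% on the fused unbalanced phone set) are generator
contracts, not claims about deployment.

# Known limitations

* The watch's hold-last-value repair means sedentary watch windows carry
  the *previous* bout's terminal orientation; watch-side sitting/standing
  discrimination is accordingly weak by construction.
* The distance feature is a within-window oscillation proxy; it is not
  comparable across activities with different duty cycles.
* The magnetometer angle's reference (field vector vs device Y) follows the
  same convention as the accelerometer angle; other conventions exist.
* Barometric altitude assumes the standard atmosphere; absolute altitudes
  are only as good as the sea-level reference, though within-window
  differences are insensitive to it.
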