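# harwear

Activity recognition from smartphone and smartwatch sensor streams.

`harwear` is for researchers prototyping human activity recognition (HAR)
pipelines on body-worn consumer devices. It implements the full chain from
raw multi-rate sensor streams to cross-validated classification results:

* **ingestion** of irregularly timestamped streams (phone tri-axial
  accelerometer ~90 Hz, magnetometer ~25 Hz, gyroscope ~27 Hz, barometer
  ~5 Hz, light, GPS fixes; watch accelerometer ~15 Hz), with
  hold-last-value repair of sensor power-downs and linear resampling to
  fixed rates (100 Hz inertial, 10 Hz pressure/light);
* **filtering** with a zero-phase 4th-order Butterworth bank: a 0.6 Hz
  low-pass isolating the static (gravity) component, a 0.6–7.5 Hz
  band-pass isolating gait-band dynamics, and a 0.1 Hz high-pass
  detrending barometric pressure;
* **features** on non-overlapping 2 s windows: 53 phone attributes
  (actigraphy counts, device angles, per-axis spectral peaks, step counts,
  oscillatory displacement, barometric altitude change and slope) and a
  17-attribute watch accelerometry subset;
* **datasets**: per-sensor column subsets, balanced (equal-count
  subsampled) and unbalanced variants, CSV and ARFF interchange;
* **evaluation**: stratified 10-fold cross-validation of five classifiers
  (information-gain and Gini decision trees, naive Bayes, a single-layer
  perceptron, an RBF SVM), optional PCA reduction at 95% explained
  variance, and per-class / overall true-positive reports;
* **indoor/outdoor detection** fusing GPS visibility features (satellite
  count and SNR collapse indoors) with ambient light features.

Because study recordings of this kind are rarely deposited, the package
includes a seeded **synthetic session generator** (`simulate_session()`,
`simulate_cohort()`, `simulate_transition_walk()`) producing physically
plausible multi-sensor recordings with ground-truth annotations: harmonic
gait waveforms at activity-specific cadence and intensity,
posture-dependent gravity orientation, barometric elevator/stair altitude
tracks, watch accelerometer dropout during sedentary bouts, and
indoor/outdoor contrasts in lux and satellite visibility. The generator is
tested, first-class code: its ground truth is what the rest of the
pipeline is validated against.

## The core quantities

An **activity count** is the rectified integral of the band-passed signal
over a window, `sum(|x|) * dt` — the classical actigraphy intensity
measure. Windowed spectra use the raw periodogram (0.5 Hz resolution at
2 s / 100 Hz); the **primary frequency** is the bin maximising power summed
over the three axes. Altitude derives from pressure through the
international barometric formula `h = 44330 (1 − (p/1013.25)^{1/5.255})`.
The **overall true-positive rate** of an evaluation is
`100 · trace(C) / sum(C)` for confusion matrix `C`; with nine balanced
classes each activity can contribute at most `100/9 ≈ 11.1%` of it.

## Worked example

```r
library(harwear)

# three virtual subjects executing the default ten-minute protocol
cohort   <- simulate_cohort(3, seed = 42)
features <- lapply(cohort, extract_features)
phone    <- do.call(rbind, lapply(features, `[[`, "phone"))

fused <- build_dataset(phone, "phone", "fused")
table(fused$label)
#>          walking          running          cycling         standing
#>              225               90              180               90
#>          sitting  elevator_ascent elevator_descent     stair_ascent
#>              135               45               45               45
#>    stair_descent
#>               45

train_eval(fused, "cart", folds = 10, seed = 42)
#> <eval_report> cart: overall TP 99.44% (900 instances, 10-fold CV)

balanced <- balance_dataset(fused, seed = 42)
train_eval(balanced, "cart", folds = 10, seed = 42)
#> <eval_report> cart: overall TP 97.53% (405 instances, 10-fold CV)

red <- pca_reduce(fused, 0.95)
red$k
#> [1] 23   # components covering 95% of the standardized variance

# indoor -> outdoor transition walk; GPS, light, and fused detection
geo <- geo_feature_table(simulate_transition_walk(seed = 42))
sapply(detect_environment(geo, "nb", folds = 10, seed = 42),
       function(r) r$overall_tp_pct)
#>   gps light fused
#>   100   100   100
```

The first report says the Gini tree recovers 99.44% of the 900 window
labels out-of-fold on the unbalanced set; balancing (equal class counts,
here 45 windows per activity) makes the rarer stair/elevator classes count
equally and lowers the overall rate. The final line is the indoor/outdoor
experiment: on cleanly separated synthetic conditions all three feature
sets achieve a 100% true-positive rate, with fusion never below either
single sensor.

A command-line wrapper over the same functions lives at
`inst/cli/harwear.R`:

```sh
Rscript inst/cli/harwear.R simulate --seed 7 --out run1
Rscript inst/cli/harwear.R extract-features --out run1
Rscript inst/cli/harwear.R build-datasets --out run1
Rscript inst/cli/harwear.R evaluate --out run1
Rscript inst/cli/harwear.R detect-environment --out run1
Rscript inst/cli/harwear.R report --out run1
```

## Package layout

* `R/synthgen.R` — activity profiles, device specs, session/cohort/walk
  generators
* `R/signal_io.R` — recording CSV dialect, resampling, hold-last filling
* `R/filters.R` — the zero-phase Butterworth bank
* `R/windowing.R`, `R/features_inertial.R`, `R/features_geo.R` — windows
  and the 53/17/8-attribute feature sets
* `R/dataset.R`, `R/modeling.R` — dataset assembly, balancing, CSV/ARFF,
  cross-validated evaluation, PCA, the experiment matrix
* `R/cli.R` — the command-line orchestration
* `vignettes/harwear-methods.Rmd` — signal models, numeric choices, and
  the limits of synthetic validation
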