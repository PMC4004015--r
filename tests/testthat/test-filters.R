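test_that("band-pass gain meets the gait-band contract", {
  expect_gte(measure_gain(dynamic_bandpass, 2), 0.9)
  expect_lte(measure_gain(dynamic_bandpass, 15), 0.1)
  expect_lte(measure_gain(dynamic_bandpass, 0.1), 0.1)
  # DC rejection: constant input maps to ~0
  const <- uniform_signal("phone", "accelerometer", 100, 0,
                          matrix(5, nrow = 2000, ncol = 3))
  expect_lt(max(abs(dynamic_bandpass(const)$values)), 0.05)
})

test_that("gravity low-pass passes DC and rejects gait frequencies", {
  const <- uniform_signal("phone", "accelerometer", 100, 0,
                          matrix(9.81, nrow = 2000, ncol = 3))
  out <- gravity_lowpass(const)
  expect_equal(mean(out$values[, 2]), 9.81, tolerance = 0.02 * 9.81)
  expect_gte(measure_gain(gravity_lowpass, 0.05, dur_s = 120), 0.95)
  expect_lte(measure_gain(gravity_lowpass, 3), 0.1)
})

test_that("pressure high-pass removes drift and keeps fast ripple", {
  rate <- 10
  t <- seq(0, 600 - 1 / rate, by = 1 / rate)
  drift <- 0.5 / 3600 * t            # 0.5 hPa per hour
  ripple <- 0.2 * sin(2 * pi * 1 * t)
  sig <- uniform_signal("phone", "pressure", rate, 0,
                        matrix(1013 + drift + ripple, ncol = 1))
  out <- pressure_highpass(sig)$values[, 1]
  mid <- seq(floor(length(t) / 4), ceiling(3 * length(t) / 4))
  # drift component attenuated at least 10x
  fitted <- lm(out[mid] ~ t[mid])
  expect_lt(abs(coef(fitted)[2]), (0.5 / 3600) / 10)
  # ripple amplitude preserved within 10%
  expect_equal(sqrt(2) * central_rms(out - mean(out)), 0.2, tolerance = 0.1)
  # constant pressure maps to ~0
  const <- uniform_signal("phone", "pressure", 10, 0, matrix(1013, 3000, 1))
  expect_lt(max(abs(pressure_highpass(const)$values)), 1e-6)
})

test_that("filters are linear and the gravity/dynamic split conserves band-limited input", {
  t <- seq(0, 60 - 0.01, by = 0.01)
  x <- sin(2 * pi * 2 * t)
  y <- cos(2 * pi * 3 * t)
  mk <- function(v) uniform_signal("phone", "accelerometer", 100, 0, cbind(v, 0 * v, 0 * v))
  lhs <- dynamic_bandpass(mk(2 * x + 3 * y))$values[, 1]
  rhs <- 2 * dynamic_bandpass(mk(x))$values[, 1] + 3 * dynamic_bandpass(mk(y))$values[, 1]
  expect_lt(max(abs(lhs - rhs)), 1e-6)

  # one slow + one gait tone: low-pass + band-pass recovers the signal
  comb <- 9 + sin(2 * pi * 2 * t)
  rec <- gravity_lowpass(mk(comb))$values[, 1] + dynamic_bandpass(mk(comb))$values[, 1]
  mid <- 1000:5000
  expect_equal(rec[mid], comb[mid], tolerance = 0.05)
})

test_that("zero-phase filtering keeps windows aligned with raw time", {
  t <- seq(0, 60 - 0.01, by = 0.01)
  x <- sin(2 * pi * 2 * t)
  sig <- uniform_signal("phone", "accelerometer", 100, 0, cbind(x, 0 * t, 0 * t))
  out <- dynamic_bandpass(sig)$values[, 1]
  mid <- 1000:5000
  # in-band tone passes with no lag: max correlation at zero shift
  shifts <- -5:5
  cors <- vapply(shifts, function(s) cor(out[mid], x[mid + s]), numeric(1))
  expect_equal(shifts[which.max(cors)], 0)
})

test_that("filter cutoffs at or above Nyquist are rejected", {
  cfg <- pipeline_config()
  sig <- tone_signal(2, dur_s = 10)
  bad <- cfg
  bad$gravity_lowpass_cutoff_hz <- 60
  expect_error(gravity_lowpass(sig, bad), "Nyquist")
  expect_error(pipeline_config(bandpass_hz = c(0.6, 60)), "Nyquist")
})

test_that("gravity magnitude survives the low-pass on a sitting trace", {
  ses <- simulate_session(list(list(profile = "sitting", duration_s = 30)),
                          devices = list(device_spec("phone")), seed = 9)
  acc <- resample_linear(ses$streams$phone$accelerometer, 100)
  grav <- gravity_lowpass(acc)
  mags <- sqrt(rowSums(grav$values^2))
  mid <- seq(floor(length(mags) / 4), ceiling(3 * length(mags) / 4))
  expect_equal(mean(mags[mid]), 9.81, tolerance = 0.02 * 9.81)
})
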