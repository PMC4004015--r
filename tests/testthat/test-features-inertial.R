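rate <- 100
t2s <- seq(0, 2 - 1 / rate, by = 1 / rate)  # one 2 s window

test_that("activity counts equal the rectified integral and scale linearly", {
  tone <- cbind(sin(2 * pi * 2 * t2s), 0, 0)
  counts <- activity_counts(tone, rate)
  # closed form: mean of |sin| is 2/pi, over 2 s the integral is 4/pi
  expect_equal(unname(counts[1]), 4 / pi, tolerance = 0.02)
  expect_equal(unname(counts[2]), 0)
  expect_equal(activity_counts(2 * tone, rate), 2 * counts)
  expect_equal(unname(activity_counts(matrix(0, 200, 3), rate)), rep(0, 3))
})

test_that("RMS counts reduce to the single-axis RMS for one-axis signals", {
  tone <- cbind(sin(2 * pi * 2 * t2s), 0, 0)
  expect_equal(rms_counts(tone), sqrt(mean(tone[, 1]^2)))
  expect_equal(rms_counts(matrix(0, 200, 3)), 0)
})

test_that("coefficient of variation matches the rectified-sinusoid closed form", {
  tone <- sin(2 * pi * 2 * t2s)
  cv <- coefficients_of_variation(cbind(tone, tone * 5, 0))
  expect_equal(unname(cv[1]), sqrt(pi^2 / 8 - 1), tolerance = 0.02)
  expect_equal(unname(cv[2]), unname(cv[1]))       # scale invariance
  expect_equal(unname(cv[3]), 0)                   # zero-mean convention
  expect_equal(unname(coefficients_of_variation(matrix(2, 200, 1))[1]), 0)
})

test_that("spectral features locate on-bin tones exactly", {
  x <- cbind(sin(2 * pi * 3 * t2s), sin(2 * pi * 1.5 * t2s), 0)
  sp <- spectral_features(x, rate)
  expect_equal(sp$peak_freq[1], 3.0)
  expect_equal(sp$peak_freq[2], 1.5)
  expect_equal(sp$peak_freq[3], 0)
  expect_equal(sp$primary_freq, 3.0)   # x axis is the strongest bin overall
  expect_equal(sp$peak_power, max(sp$max_power))
  z <- spectral_features(matrix(0, 200, 3), rate)
  expect_equal(z$max_power, rep(0, 3))
  expect_equal(z$peak_freq, rep(0, 3))
  expect_equal(z$primary_freq, 0)
})

test_that("step count finds cyclical peaks and tolerates noise", {
  tone <- sin(2 * pi * 2 * t2s)
  expect_equal(step_count(tone, rate), 4L)
  expect_equal(step_count(rep(0, 200), rate), 0L)
  set.seed(42)
  hits <- vapply(1:20, function(i) {
    step_count(tone + rnorm(200, 0, 0.1), rate)
  }, numeric(1))
  expect_true(all(abs(hits - 4) <= 1))
})

test_that("estimated distance recovers sinusoidal displacement amplitude", {
  a <- 2; f <- 2
  x <- cbind(a * sin(2 * pi * f * t2s), 0, 0)
  expect_equal(estimated_distance(x, rate), a / (2 * pi * f)^2, tolerance = 0.05)
  expect_equal(estimated_distance(matrix(0, 200, 3), rate), 0)
  # constant acceleration is removed by the detrend: oscillatory proxy only
  expect_lt(estimated_distance(matrix(c(rep(1, 200), rep(0, 400)), 200), rate), 1e-10)
})

test_that("altitude features follow the barometric formula", {
  # 0.12 hPa linear fall over one window near sea level ~ +1 m climbed
  p <- seq(1013.25, 1013.25 - 0.12, length.out = 20)
  af <- altitude_features(p, 10)
  expect_equal(af$altitude_diff, 1.0, tolerance = 0.05)
  expect_equal(af$altitude_slope, af$altitude_diff / 1.9, tolerance = 0.05)
  cf <- altitude_features(rep(1000, 20), 10)
  expect_equal(cf$altitude_diff, 0)
  expect_equal(cf$altitude_slope, 0)
  expect_error(altitude_features(c(-1, 5), 10), "positive")
})

test_that("device angles measure orientation against the +Y axis", {
  along_y <- matrix(rep(c(0, 9.81, 0), each = 50), ncol = 3)
  along_x <- matrix(rep(c(9.81, 0, 0), each = 50), ncol = 3)
  expect_equal(mean_device_angle(along_y, FALSE), 0)
  expect_equal(mean_device_angle(along_y, TRUE), 0)
  expect_equal(mean_device_angle(along_x, FALSE), 90)
  expect_equal(mean_device_angle(along_x, TRUE), 90)
  expect_true(is.na(mean_device_angle(matrix(0.01, 50, 3), TRUE, 9.81)))
})

test_that("phone and watch schemas have exactly 53 and 17 stable attributes", {
  expect_length(feature_schema("phone"), 53)
  expect_length(feature_schema("watch"), 17)
  fx <- walking_session_features()$phone
  feats <- setdiff(names(fx), c("device", "segment_id", "window_idx", "label"))
  expect_identical(feats, feature_schema("phone"))
  expect_true(all(vapply(fx[feats], is.numeric, logical(1))))
  expect_true(all(is.finite(as.matrix(fx[feats]))))
  # angles within [0, 180], frequencies within [0, Nyquist], counts >= 0
  expect_true(all(fx$angle_acc_corrected >= 0 & fx$angle_acc_corrected <= 180))
  expect_true(all(fx$peak_freq_acc_y >= 0 & fx$peak_freq_acc_y <= 50))
  expect_true(all(fx$step_count_acc_y >= 0))
})

test_that("a window with a missing sensor slice is rejected", {
  win <- list(label = "walking", slices = list(acc_dyn = matrix(0, 200, 3)))
  expect_error(compute_phone_features(win), "lacks sensor slice")
  expect_error(compute_watch_features(win), "lacks sensor slice")
})

test_that("generator truth is recovered: posture angle and intensity ordering", {
  prof <- activity_profile("sitting", gravity_axis_angle_deg = 40)
  ses <- simulate_session(list(list(profile = prof, duration_s = 30)),
                          devices = list(device_spec("phone")), seed = 21)
  fx <- extract_features(ses)$phone
  expect_true(all(abs(fx$angle_acc_corrected - 40) < 2))

  walk <- walking_session_features()$phone
  expect_gt(min(walk$rms_count_acc), max(fx$rms_count_acc))
  expect_gt(min(walk$count_acc_y), max(fx$count_acc_y))
})
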