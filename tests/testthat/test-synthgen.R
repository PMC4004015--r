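test_that("identical seeds give bit-identical sessions and segments partition the span", {
  proto <- list(list(profile = "walking", duration_s = 20),
                list(profile = "sitting", duration_s = 15))
  a <- simulate_session(proto, seed = 7)
  b <- simulate_session(proto, seed = 7)
  expect_identical(a, b)
  c <- simulate_session(proto, seed = 8)
  expect_false(identical(a$streams, c$streams))

  segs <- a$segments[a$segments$device == "phone", ]
  expect_equal(segs$label, c("walking", "sitting"))
  expect_equal(segs$start_ms, c(0, 20000))
  expect_equal(segs$end_ms, c(20000, 35000))
  # every phone stream covers the protocol span
  for (st in a$streams$phone) {
    expect_lte(st$t_ms[1], 0)
    expect_gte(max(st$t_ms), 35000)
  }
})

test_that("degenerate protocols are rejected", {
  expect_error(simulate_session(list(), seed = 1), "at least one")
  expect_error(simulate_session(list(list(profile = "jogging", duration_s = 10))))
  expect_error(simulate_session(list(list(profile = "walking", duration_s = -5))),
               "positive duration")
  expect_error(activity_profile("walking", gait_frequency_hz = 9), "\\[0, 7.5\\]")
  expect_error(simulate_transition_walk(indoor_s = -1), "positive")
})

test_that("sampling rates match the device spec within 10%", {
  ses <- simulate_session(list(list(profile = "walking", duration_s = 30)), seed = 3)
  nominal <- c(accelerometer = 90, magnetometer = 25, gyroscope = 27, pressure = 5)
  for (kind in names(nominal)) {
    st <- ses$streams$phone[[kind]]
    expect_lt(abs(median(diff(st$t_ms)) - 1000 / nominal[[kind]]),
              0.1 * 1000 / nominal[[kind]], label = kind)
  }
  watch <- ses$streams$watch$accelerometer
  expect_lt(abs(median(diff(watch$t_ms)) - 1000 / 15), 0.1 * 1000 / 15)
})

test_that("gait fundamental is recoverable from the band-passed trace", {
  ses <- simulate_session(list(list(profile = "walking", duration_s = 60)),
                          devices = list(device_spec("phone")), seed = 7)
  acc <- resample_linear(ses$streams$phone$accelerometer, 100)
  dyn <- dynamic_bandpass(acc)
  # independent oracle: direct periodogram of the generated y-axis trace
  f_est <- oracle_peak_freq(dyn$values[2001:4000, "y"], 100)
  expect_lt(abs(f_est - 2.0), 0.5 + 1e-9)
})

test_that("static postures carry no dynamic component above the noise floor", {
  ses <- simulate_session(list(list(profile = "sitting", duration_s = 60)),
                          devices = list(device_spec("phone")), seed = 7)
  acc <- resample_linear(ses$streams$phone$accelerometer, 100)
  dyn <- dynamic_bandpass(acc)
  noise_sd <- device_spec("phone")$noise_sd[["accelerometer"]]
  for (j in 1:3) expect_lt(central_rms(dyn$values[, j]), 3 * noise_sd)
})

test_that("watch accelerometer drops out during sedentary bouts only", {
  proto <- list(list(profile = "walking", duration_s = 20),
                list(profile = "sitting", duration_s = 30),
                list(profile = "walking", duration_s = 20))
  ses <- simulate_session(proto, devices = list(device_spec("watch")), seed = 5)
  tt <- ses$streams$watch$accelerometer$t_ms
  expect_false(any(tt >= 20000 & tt < 50000))
  # active bouts: at least one sample per 2x nominal interval (2/15 s)
  active <- tt[tt < 20000]
  expect_lt(max(diff(active)), 2 * 1000 / 15)
})

test_that("transition walks contrast lux and satellite visibility indoors vs outdoors", {
  walk <- simulate_transition_walk(indoor_s = 300, outdoor_s = 300, seed = 1)
  lux <- walk$light$values[, 1]
  indoor <- walk$light$t_ms < walk$transition_ms
  expect_gt(mean(lux[!indoor]), mean(lux[indoor]))
  # indoors GPS is invisible: no fixes before the transition
  expect_false(any(walk$gps$t_ms < walk$transition_ms))
  expect_gt(mean(walk$gps$values[, "sat_count"]), 7)
  expect_equal(walk$transition_ms, 300000)
})

test_that("pressure follows the barometric altitude track through an elevator ride", {
  proto <- list(list(profile = "standing", duration_s = 20),
                list(profile = "elevator_ascent", duration_s = 30),
                list(profile = "standing", duration_s = 20))
  ses <- simulate_session(proto, devices = list(device_spec("phone")), seed = 2)
  p <- ses$streams$phone$pressure
  alt <- pressure_to_altitude(p$values[, 1])
  before <- mean(alt[p$t_ms < 15000])
  after <- mean(alt[p$t_ms > 55000])
  # 1 m/s for 30 s => ~30 m gained
  expect_lt(abs((after - before) - 30), 2)
})
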