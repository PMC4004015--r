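# Shared fixtures, built lazily once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A pure tone packaged as a 100 Hz inertial uniform signal (x axis carries
# the tone, y and z are zero).
tone_signal <- function(freq_hz, dur_s = 60, rate_hz = 100, amp = 1,
                        kind = "accelerometer") {
  t <- seq(0, dur_s - 1 / rate_hz, by = 1 / rate_hz)
  uniform_signal("phone", kind, rate_hz, 0,
                 cbind(x = amp * sin(2 * pi * freq_hz * t), y = 0 * t, z = 0 * t))
}

# RMS of the central half of a vector (avoids residual edge transients when
# measuring filter gains).
central_rms <- function(x) {
  n <- length(x)
  sqrt(mean(x[floor(n / 4):ceiling(3 * n / 4)]^2))
}

# Measured zero-phase gain of a filter function at one frequency.
measure_gain <- function(filter_fun, freq_hz, rate_hz = 100, dur_s = 60,
                         kind = "accelerometer", ...) {
  sig <- tone_signal(freq_hz, dur_s, rate_hz, kind = kind)
  out <- filter_fun(sig, ...)
  central_rms(out$values[, 1]) / central_rms(sig$values[, 1])
}

# Independent periodogram peak (plain fft, no package code path shared with
# spectral_features' callers).
oracle_peak_freq <- function(x, rate_hz) {
  n <- length(x)
  p <- Mod(fft(x))^2
  k <- 1:floor(n / 2)          # skip DC
  k[which.max(p[k + 1])] * rate_hz / n
}

# Small three-subject cohort used by several modeling tests.
small_cohort_features <- function() {
  fixture("small_cohort", function() {
    cohort <- simulate_cohort(3, seed = 101)
    fx <- lapply(cohort, extract_features)
    list(phone = do.call(rbind, lapply(fx, `[[`, "phone")),
         watch = do.call(rbind, lapply(fx, `[[`, "watch")))
  })
}

# One 60 s walking session on the phone, processed to features.
walking_session_features <- function() {
  fixture("walking60", function() {
    ses <- simulate_session(list(list(profile = "walking", duration_s = 60)),
                            devices = list(device_spec("phone")), seed = 7)
    extract_features(ses)
  })
}
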