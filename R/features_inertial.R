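# Feature schema -----------------------------------------------------------

axes <- c("x", "y", "z")

.phone_feature_names <- c(
  paste0("count_acc_", axes), paste0("count_mag_", axes),          # 6
  "rms_count_acc", "rms_count_mag",                                # 2
  "angle_acc_mean", "angle_mag_mean",                              # 2
  "angle_acc_corrected",                                           # 1
  paste0("cv_acc_", axes), paste0("cv_mag_", axes),                # 6
  paste0("max_power_acc_", axes), paste0("max_power_gyro_", axes),
  paste0("max_power_mag_", axes),                                  # 9
  paste0("peak_freq_acc_", axes), paste0("peak_freq_gyro_", axes),
  paste0("peak_freq_mag_", axes),                                  # 9
  "peak_power_acc", "peak_power_gyro", "peak_power_mag",           # 3
  "primary_freq_acc", "primary_freq_gyro", "primary_freq_mag",     # 3
  paste0("step_count_acc_", axes), paste0("step_count_gyro_", axes),
  paste0("step_count_mag_", axes),                                 # 9
  "est_distance_acc",                                              # 1
  "altitude_diff", "altitude_slope"                                # 2
)

.watch_feature_names <- c(
  paste0("count_acc_", axes), "rms_count_acc",
  paste0("peak_freq_acc_", axes), paste0("max_power_acc_", axes),
  "peak_power_acc", "primary_freq_acc",
  paste0("step_count_acc_", axes),
  "angle_acc_mean", "angle_acc_corrected"
)

#' Feature schemas
#'
#' Names of the per-window attributes: 53 for the phone (accelerometer,
#' magnetometer, gyroscope and pressure) and the 17-attribute accelerometry
#' subset for the watch.
#'
#' @param device `"phone"` or `"watch"`.
#' @return character vector of attribute names.
#' @export
#' @examples
#' length(feature_schema("phone"))  # 53
#' length(feature_schema("watch"))  # 17
feature_schema <- function(device = c("phone", "watch")) {
  device <- match.arg(device)
  if (device == "phone") .phone_feature_names else .watch_feature_names
}

# Columns of the phone schema attributable to each sensor, used by the
# dataset builder's sensor-subset restriction.
feature_sensor_columns <- function(sensor) {
  nm <- .phone_feature_names
  switch(sensor,
    accelerometer = nm[grepl("_acc(_|$)", nm)],
    magnetometer = nm[grepl("_mag(_|$)", nm)],
    gyro = nm[grepl("_gyro(_|$)", nm)],
    pressure = c("altitude_diff", "altitude_slope"),
    fused = nm,
    stop("unknown sensor subset: ", sensor)
  )
}

# Elementary window operations ---------------------------------------------

#' Actigraphy activity counts
#'
#' The classical epoch count: the rectified integral of the band-passed
#' signal per axis, i.e. `sum(|x|) * dt`. Scales linearly with dynamic
#' amplitude and is zero for static postures.
#'
#' @param x numeric matrix (samples x axes) of band-passed values.
#' @param rate_hz sampling rate of the window.
#' @return one count per column of `x`.
#' @export
activity_counts <- function(x, rate_hz) {
  x <- as.matrix(x)
  colSums(abs(x)) / rate_hz
}

#' Vector-magnitude RMS count
#'
#' Root mean square of the per-sample vector magnitude of a band-passed
#' 3-axis signal over the window.
#'
#' @param x numeric matrix (samples x 3).
#' @return scalar, non-negative.
#' @export
rms_counts <- function(x) {
  x <- as.matrix(x)
  sqrt(mean(rowSums(x^2)))
}

#' Mean device angle relative to the Y axis
#'
#' The vertical reference is the device +Y axis. Uncorrected: the mean over
#' samples of the angle between the instantaneous (low-passed) field vector
#' and +Y. Corrected: the angle between the window's mean vector and +Y.
#' Windows whose mean vector magnitude falls below 10% of the expected
#' field are flagged missing (`NA`).
#'
#' @param x low-passed 3-axis matrix (gravity or magnetic field).
#' @param corrected logical; see above.
#' @param expected_magnitude nominal field strength (9.81 m/s^2 for the
#'   accelerometer, ~50 uT for the magnetometer).
#' @return angle in degrees in `[0, 180]`, or `NA`.
#' @export
mean_device_angle <- function(x, corrected = FALSE, expected_magnitude = 9.81) {
  x <- as.matrix(x)
  mags <- sqrt(rowSums(x^2))
  if (mean(mags) < 0.1 * expected_magnitude) return(NA_real_)
  if (corrected) {
    v <- colMeans(x)
    acos(min(1, max(-1, v[2] / sqrt(sum(v^2))))) * 180 / pi
  } else {
    cosang <- pmin(1, pmax(-1, x[, 2] / pmax(mags, .Machine$double.eps)))
    mean(acos(cosang)) * 180 / pi
  }
}

#' Coefficient of variation of the rectified signal
#'
#' `sd(|x|) / mean(|x|)` per axis. Rectification avoids the near-zero mean
#' of band-passed signals; a rectified mean below machine tolerance yields
#' 0 by convention. Scale-invariant.
#'
#' @param x band-passed matrix (samples x axes).
#' @return one CV per column.
#' @export
coefficients_of_variation <- function(x) {
  x <- as.matrix(x)
  apply(x, 2, function(col) {
    r <- abs(col)
    m <- mean(r)
    if (m < 1e-12) 0 else sd(r) / m
  })
}

# One-sided periodogram: power |X_k|^2 / n at frequencies k * rate / n,
# k = 0 .. n/2.
periodogram <- function(col, rate_hz) {
  n <- length(col)
  p <- Mod(fft(col))^2 / n
  k <- 0:floor(n / 2)
  list(freq = k * rate_hz / n, power = p[k + 1])
}

#' Spectral peak features of a 3-axis window
#'
#' Per axis: the maximum periodogram power (`max_power`) and its bin
#' frequency (`peak_freq`, excluding DC). Across axes: `peak_power`, the
#' largest of the three maxima, and `primary_freq`, the frequency of the
#' bin maximising power summed over axes. A 2 s window at 100 Hz gives a
#' 0.5 Hz frequency resolution. All-zero input returns zero powers and
#' frequency 0 by convention.
#'
#' @param x band-passed matrix (samples x 3).
#' @param rate_hz sampling rate.
#' @return list with `max_power` (3), `peak_freq` (3), `peak_power` (1),
#'   `primary_freq` (1).
#' @export
spectral_features <- function(x, rate_hz) {
  x <- as.matrix(x)
  pg <- lapply(seq_len(ncol(x)), function(j) periodogram(x[, j], rate_hz))
  freqs <- pg[[1]]$freq
  nd <- seq_along(freqs)[-1]  # exclude DC from peak search
  max_power <- numeric(ncol(x))
  peak_freq <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    pw <- pg[[j]]$power[nd]
    i <- which.max(pw)
    max_power[j] <- pw[i]
    peak_freq[j] <- if (pw[i] < 1e-12) 0 else freqs[nd][i]
  }
  total <- Reduce(`+`, lapply(pg, function(g) g$power[nd]))
  ip <- which.max(total)
  list(max_power = max_power, peak_freq = peak_freq,
       peak_power = max(max_power),
       primary_freq = if (total[ip] < 1e-12) 0 else freqs[nd][ip])
}

#' Cyclical peak (step) count
#'
#' Counts local maxima exceeding an adaptive threshold of `thresh_frac`
#' times the window RMS of the axis, with a minimum peak separation
#' (default 0.25 s, i.e. a 4 Hz cadence ceiling inside the gait band).
#' Candidates are accepted tallest-first under the separation constraint.
#'
#' @param x band-passed vector (one axis).
#' @param rate_hz sampling rate.
#' @param thresh_frac threshold as a fraction of window RMS.
#' @param min_separation_s minimum spacing between accepted peaks.
#' @return integer count, >= 0.
#' @export
step_count <- function(x, rate_hz, thresh_frac = 0.5, min_separation_s = 0.25) {
  n <- length(x)
  rms <- sqrt(mean(x^2))
  if (rms < 1e-12 || n < 3) return(0L)
  thr <- thresh_frac * rms
  i <- 2:(n - 1)
  cand <- i[x[i] > x[i - 1] & x[i] >= x[i + 1] & x[i] >= thr]
  if (length(cand) == 0) return(0L)
  cand <- cand[order(x[cand], decreasing = TRUE)]
  min_gap <- min_separation_s * rate_hz
  kept <- integer(0)
  for (c0 in cand) {
    if (all(abs(kept - c0) >= min_gap)) kept <- c(kept, c0)
  }
  length(kept)
}

cumtrapz1 <- function(x, dt) c(0, cumsum((x[-1] + x[-length(x)]) / 2)) * dt

#' Oscillatory displacement estimate
#'
#' Double trapezoidal integration of each band-passed accelerometer axis
#' with a zero-mean detrend before each integration stage (so any residual
#' DC cannot accumulate quadratically), then the Euclidean norm over axes
#' of the per-axis peak displacement. A rough proxy for distance travelled
#' within the window: it measures oscillatory displacement, not net
#' translation.
#'
#' @param x band-passed accelerometer matrix (samples x 3), m/s^2.
#' @param rate_hz sampling rate.
#' @return displacement in metres, >= 0.
#' @export
estimated_distance <- function(x, rate_hz) {
  x <- as.matrix(x)
  dt <- 1 / rate_hz
  amp <- apply(x, 2, function(a) {
    v <- cumtrapz1(a - mean(a), dt)
    d <- cumtrapz1(v - mean(v), dt)
    max(abs(d - mean(d)))
  })
  sqrt(sum(amp^2))
}

#' Barometric altitude features
#'
#' Converts the raw pressure slice to altitude via the international
#' barometric formula and reports the within-window altitude change
#' (last minus first) and the least-squares slope of altitude against time
#' (m/s). Raw (not high-passed) pressure is used so absolute differences
#' are meaningful.
#'
#' @param p_hpa raw pressure vector, hPa.
#' @param rate_hz sampling rate.
#' @return list with `altitude_diff` (m) and `altitude_slope` (m/s).
#' @export
altitude_features <- function(p_hpa, rate_hz) {
  alt <- pressure_to_altitude(p_hpa)
  t_s <- (seq_along(alt) - 1) / rate_hz
  tc <- t_s - mean(t_s)
  slope <- sum(tc * (alt - mean(alt))) / sum(tc^2)
  list(altitude_diff = alt[length(alt)] - alt[1], altitude_slope = slope)
}

# Per-window assembly -------------------------------------------------------

inertial_block <- function(dyn, rate_hz, sensor) {
  sp <- spectral_features(dyn, rate_hz)
  out <- c(setNames(as.numeric(sp$max_power), paste0("max_power_", sensor, "_", axes)),
           setNames(as.numeric(sp$peak_freq), paste0("peak_freq_", sensor, "_", axes)),
           setNames(sp$peak_power, paste0("peak_power_", sensor)),
           setNames(sp$primary_freq, paste0("primary_freq_", sensor)),
           setNames(vapply(seq_len(3), function(j) as.numeric(step_count(dyn[, j], rate_hz)),
                           numeric(1)),
                    paste0("step_count_", sensor, "_", axes)))
  out
}

#' Compute the 53-attribute phone feature vector for one window
#'
#' Expects a window (see [extract_windows()]) whose slices include the
#' band-passed and low-passed accelerometer and magnetometer, band-passed
#' gyroscope, and raw pressure: slice names `acc_dyn`, `acc_grav`,
#' `mag_dyn`, `mag_low`, `gyro_dyn`, `pressure`.
#'
#' @param window a window object.
#' @return named numeric vector of length 53 (angles may be `NA` when the
#'   field magnitude collapses).
#' @export
compute_phone_features <- function(window) {
  need <- c("acc_dyn", "acc_grav", "mag_dyn", "mag_low", "gyro_dyn", "pressure")
  missing <- setdiff(need, names(window$slices))
  if (length(missing) > 0)
    stop("window lacks sensor slice(s): ", paste(missing, collapse = ", "))
  s <- window$slices
  r <- attr(s$acc_dyn, "rate_hz")
  rp <- attr(s$pressure, "rate_hz")
  altf <- altitude_features(as.numeric(s$pressure), rp)
  out <- c(
    setNames(activity_counts(s$acc_dyn, r), paste0("count_acc_", axes)),
    setNames(activity_counts(s$mag_dyn, r), paste0("count_mag_", axes)),
    rms_count_acc = rms_counts(s$acc_dyn),
    rms_count_mag = rms_counts(s$mag_dyn),
    angle_acc_mean = mean_device_angle(s$acc_grav, FALSE, 9.81),
    angle_mag_mean = mean_device_angle(s$mag_low, FALSE, 50),
    angle_acc_corrected = mean_device_angle(s$acc_grav, TRUE, 9.81),
    setNames(coefficients_of_variation(s$acc_dyn), paste0("cv_acc_", axes)),
    setNames(coefficients_of_variation(s$mag_dyn), paste0("cv_mag_", axes)),
    inertial_block(s$acc_dyn, r, "acc"),
    inertial_block(s$gyro_dyn, r, "gyro"),
    inertial_block(s$mag_dyn, r, "mag"),
    est_distance_acc = estimated_distance(s$acc_dyn, r),
    altitude_diff = altf$altitude_diff,
    altitude_slope = altf$altitude_slope
  )
  out[.phone_feature_names]
}

#' Compute the 17-attribute watch feature vector for one window
#'
#' Accelerometry subset: counts, vector-magnitude RMS, per-axis spectral
#' peaks, peak power, primary frequency, step counts, and the mean and
#' corrected device angles. Requires slices `acc_dyn` and `acc_grav`.
#'
#' @param window a window object.
#' @return named numeric vector of length 17.
#' @export
compute_watch_features <- function(window) {
  missing <- setdiff(c("acc_dyn", "acc_grav"), names(window$slices))
  if (length(missing) > 0)
    stop("window lacks sensor slice(s): ", paste(missing, collapse = ", "))
  s <- window$slices
  r <- attr(s$acc_dyn, "rate_hz")
  out <- c(
    setNames(activity_counts(s$acc_dyn, r), paste0("count_acc_", axes)),
    rms_count_acc = rms_counts(s$acc_dyn),
    inertial_block(s$acc_dyn, r, "acc"),
    angle_acc_mean = mean_device_angle(s$acc_grav, FALSE, 9.81),
    angle_acc_corrected = mean_device_angle(s$acc_grav, TRUE, 9.81)
  )
  out[.watch_feature_names]
}

# Session-level pipeline ----------------------------------------------------

#' Extract per-window features from a recorded session
#'
#' Full processing chain for one session: hold-last-value filling, linear
#' resampling (inertial to 100 Hz, pressure to 10 Hz), the gravity/dynamic
#' filter split, two-second windowing of every accepted segment, and
#' per-window feature computation (53 phone attributes, 17 watch
#' attributes). Segments a device's signals cannot cover (e.g. a watch
#' bout before the first sample) are skipped and counted.
#'
#' @param session list with `streams` and `segments` (from
#'   [simulate_session()] or [read_recording()]).
#' @param config a [pipeline_config()].
#' @return list with `phone` and `watch` feature data frames (provenance
#'   columns `device`, `segment_id`, `window_idx`, `label`, then the
#'   schema columns) and `skipped_segments` counts.
#' @export
extract_features <- function(session, config = pipeline_config()) {
  out <- list(phone = NULL, watch = NULL,
              skipped_segments = c(phone = 0L, watch = 0L))
  for (device in names(session$streams)) {
    st <- session$streams[[device]]
    segs <- session$segments[session$segments$device == device, , drop = FALSE]
    if (nrow(segs) == 0) next
    prep <- function(stream, rate) {
      resample_linear(fill_hold_last(stream, config$max_gap_ms), rate)
    }
    signals <- list()
    if (!is.null(st$accelerometer)) {
      acc <- prep(st$accelerometer, config$inertial_rate_hz)
      signals$acc_dyn <- dynamic_bandpass(acc, config)
      signals$acc_grav <- gravity_lowpass(acc, config)
    }
    if (!is.null(st$magnetometer)) {
      mag <- prep(st$magnetometer, config$inertial_rate_hz)
      signals$mag_dyn <- dynamic_bandpass(mag, config)
      signals$mag_low <- gravity_lowpass(mag, config)
    }
    if (!is.null(st$gyroscope)) {
      gyro <- prep(st$gyroscope, config$inertial_rate_hz)
      signals$gyro_dyn <- dynamic_bandpass(gyro, config)
    }
    if (!is.null(st$pressure)) {
      signals$pressure <- prep(st$pressure, config$pressure_rate_hz)
    }
    fun <- if (device == "phone") compute_phone_features else compute_watch_features
    rows <- list()
    for (i in seq_len(nrow(segs))) {
      wins <- tryCatch(
        extract_windows(segs[i, ], signals, config$window_s, segment_id = i),
        error = function(e) NULL)
      if (is.null(wins)) {
        out$skipped_segments[device] <- out$skipped_segments[device] + 1L
        next
      }
      for (w in wins) {
        fv <- fun(w)
        rows[[length(rows) + 1L]] <- data.frame(
          device = device, segment_id = w$segment_id, window_idx = w$index,
          label = w$label, as.list(fv), check.names = FALSE,
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows) > 0) out[[device]] <- do.call(rbind, rows)
  }
  out
}
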