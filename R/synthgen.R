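# Per-activity defaults: gait fundamental (Hz), peak dynamic acceleration
# (m/s^2), mean angle between device Y axis and gravity (deg), signed
# vertical rate (m/s), and ambient/GPS context used by the transition-walk
# generator. Static postures have zero dynamic amplitude; only elevator and
# stair activities have a nonzero vertical rate.
ACTIVITY_DEFAULTS <- data.frame(
  label = c("walking", "running", "cycling", "standing", "sitting",
            "elevator_ascent", "elevator_descent",
            "stair_ascent", "stair_descent"),
  gait_frequency_hz     = c(2.0, 2.8, 1.5, 0,   0,   0,    0,    1.8,  1.9),
  dynamic_amplitude_ms2 = c(3.0, 8.0, 2.5, 0,   0,   0,    0,    4.0,  4.5),
  gravity_axis_angle_deg = c(10,  15,  80,  5,   85,  5,    5,    20,   25),
  altitude_rate_m_per_s = c(0,   0,   0,   0,   0,   1.0, -1.0,  0.35, -0.35),
  lux_mean              = c(10000, 10000, 10000, 200, 200, 150, 150, 250, 250),
  gps_visible           = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
  sat_count_mean        = c(9, 9, 9, 0, 0, 0, 0, 0, 0),
  sat_snr_mean          = c(35, 35, 35, 0, 0, 0, 0, 0, 0),
  stringsAsFactors = FALSE
)

#' Activity signal profile
#'
#' Parameters of the signal model for one activity: gait periodicity and
#' intensity of the dynamic component, the posture's mean device-to-gravity
#' angle, the signed vertical rate for elevator/stair activities, and the
#' ambient light / GPS visibility context. Defaults encode a plausible adult
#' protocol (walking at 2 Hz cadence, running at 2.8 Hz, a near-vertical
#' pants-pocket phone while standing, near-horizontal while seated, 1 m/s
#' elevators, ~0.35 m/s stair climbs).
#'
#' @param label one of the nine activity labels.
#' @param ... named overrides of any profile field.
#' @return an object of class `activity_profile`.
#' @export
#' @examples
#' activity_profile("walking", gait_frequency_hz = 1.8)
activity_profile <- function(label, ...) {
  label <- match.arg(label, ACTIVITY_DEFAULTS$label)
  p <- as.list(ACTIVITY_DEFAULTS[ACTIVITY_DEFAULTS$label == label, ])
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown) > 0) stop("unknown profile field: ", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  if (p$gait_frequency_hz < 0 || p$gait_frequency_hz > 7.5)
    stop("gait_frequency_hz must lie in [0, 7.5] (the gait pass-band)")
  structure(p, class = "activity_profile")
}

#' Device sampling specification
#'
#' Nominal per-sensor sampling rates, relative timestamp jitter, and
#' per-sensor noise levels. The phone carries accelerometer (~90 Hz),
#' magnetometer (~25 Hz), gyroscope (~27 Hz), pressure (~5 Hz), light
#' (~5 Hz) and GPS (~1 Hz); the watch carries only an accelerometer
#' (~15 Hz) that powers down during sedentary bouts (`watch_dropout`),
#' after which the last known value is held downstream.
#'
#' @param device `"phone"` or `"watch"`.
#' @param jitter_fraction half-width of the uniform timestamp jitter,
#'   relative to the nominal interval.
#' @param watch_dropout suppress watch accelerometer samples during
#'   sedentary bouts.
#' @return an object of class `device_spec`.
#' @export
device_spec <- function(device = c("phone", "watch"),
                        jitter_fraction = 0.05,
                        watch_dropout = TRUE) {
  device <- match.arg(device)
  rates <- if (device == "phone") {
    c(accelerometer = 90, magnetometer = 25, gyroscope = 27,
      pressure = 5, light = 5, gps = 1)
  } else {
    c(accelerometer = 15)
  }
  noise <- c(accelerometer = 0.05, magnetometer = 0.3, gyroscope = 0.02,
             pressure = 0.03, light = 0.1, gps = 0)
  structure(list(device = device, rates_hz = rates,
                 jitter_fraction = jitter_fraction,
                 noise_sd = noise,
                 watch_dropout = watch_dropout && device == "watch"),
            class = "device_spec")
}

# Gait waveform: fundamental plus two harmonics (relative amplitudes
# 1, 0.4, 0.15), normalised to unit peak so dynamic_amplitude_ms2 is the
# peak dynamic acceleration.
gait_wave <- function(t_s, f0, phase = 0) {
  if (f0 <= 0) return(numeric(length(t_s)))
  w <- sin(2 * pi * f0 * t_s + phase) +
    0.4 * sin(2 * pi * 2 * f0 * t_s + 2 * phase + pi / 6) +
    0.15 * sin(2 * pi * 3 * f0 * t_s + 3 * phase + pi / 3)
  tp <- seq(0, 1 / f0, length.out = 512)
  peak <- max(abs(sin(2 * pi * f0 * tp + phase) +
                  0.4 * sin(2 * pi * 2 * f0 * tp + 2 * phase + pi / 6) +
                  0.15 * sin(2 * pi * 3 * f0 * tp + 3 * phase + pi / 3)))
  w / peak
}

# Relative distribution of the dynamic component over device axes: most
# power on Y (vertical bounce for a pocket device), less on X/Z.
AXIS_WEIGHTS <- c(x = 0.4, y = 1.0, z = 0.3)

STANDARD_PRESSURE_HPA <- 1013.25

#' Convert between barometric pressure and altitude
#'
#' International barometric formula for the standard atmosphere:
#' `h = 44330 (1 - (p / p0)^(1/5.255))` with sea-level reference
#' `p0 = 1013.25` hPa, and its inverse.
#'
#' @param p_hpa pressure in hPa (must be positive).
#' @param h_m altitude in metres (below 44330).
#' @param p0 sea-level reference pressure, hPa.
#' @return altitude in metres / pressure in hPa.
#' @export
pressure_to_altitude <- function(p_hpa, p0 = STANDARD_PRESSURE_HPA) {
  if (any(!is.finite(p_hpa)) || any(p_hpa <= 0)) stop("pressure must be positive")
  44330 * (1 - (p_hpa / p0)^(1 / 5.255))
}

#' @rdname pressure_to_altitude
#' @export
altitude_to_pressure <- function(h_m, p0 = STANDARD_PRESSURE_HPA) {
  p0 * (1 - h_m / 44330)^5.255
}

# Altitude track over the whole protocol. Elevators follow a trapezoidal
# rate (ramp up, cruise, ramp down); stairs a constant rate (the gait
# oscillation rides on the accelerometer, not the track).
make_altitude_track <- function(bouts, h0 = 50) {
  ramps <- vapply(bouts, function(b) min(2, b$duration_s / 4), numeric(1))
  function(t_s) {
    h <- rep(h0, length(t_s))
    for (i in seq_along(bouts)) {
      b <- bouts[[i]]
      r <- b$profile$altitude_rate_m_per_s
      dur <- b$duration_s
      if (r != 0) {
        ramp <- ramps[i]
        cruise <- dur - 2 * ramp
        vmax <- r * dur / (cruise + ramp)  # preserves total displacement r * dur
        rel <- t_s - b$start_s
        gain <- function(x) {
          x <- pmin(pmax(x, 0), dur)
          a1 <- pmin(x, ramp)
          a2 <- pmin(pmax(x - ramp, 0), cruise)
          a3 <- pmin(pmax(x - ramp - cruise, 0), ramp)
          vmax * (a1^2 / (2 * ramp) + a2 + a3 - a3^2 / (2 * ramp))
        }
        inb <- t_s >= b$start_s
        h[inb] <- h[inb] + gain(rel[inb])  # saturates at r * dur after the bout
      }
    }
    h
  }
}

# Device->world rotation for a posture: tilt the Y axis away from gravity by
# theta about the world Z axis, then spin about the (vertical) world Y axis
# by an arbitrary azimuth. Gravity seen in the device frame depends only on
# theta; the magnetic field also rotates with azimuth.
posture_vectors <- function(theta_deg, azimuth_rad) {
  th <- theta_deg * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cos(azimuth_rad), 0, -sin(azimuth_rad),
                 0, 1, 0,
                 sin(azimuth_rad), 0, cos(azimuth_rad)), 3, 3)
  R <- Ry %*% Rz
  g_world <- c(0, 9.81, 0)          # reaction to gravity: device at rest reads +1 g up
  b_world <- c(0, -sin(pi / 3), cos(pi / 3)) * 50  # 50 uT field, 60 deg inclination
  list(gravity = drop(t(R) %*% g_world), bfield = drop(t(R) %*% b_world))
}

# Irregular timestamp grid covering [0, total_ms]: starts at 0, uniform
# jitter on each interval, extended one sample past the end so resampling
# spans the full protocol.
jittered_times <- function(total_ms, rate_hz, jitter_fraction) {
  dt <- 1000 / rate_hz
  n <- ceiling(total_ms / (dt * (1 - jitter_fraction))) + 2L
  iv <- dt * (1 + runif(n, -jitter_fraction, jitter_fraction))
  tt <- c(0, cumsum(iv))
  tt[seq_len(which(tt >= total_ms)[1])]
}

normalize_protocol <- function(protocol) {
  if (length(protocol) == 0) stop("protocol must contain at least one activity bout")
  bouts <- lapply(protocol, function(p) {
    if (inherits(p$profile, "activity_profile")) prof <- p$profile
    else if (is.character(p$profile)) prof <- activity_profile(p$profile)
    else stop("each protocol entry needs an activity_profile in $profile")
    dur <- p$duration_s
    if (!is.numeric(dur) || length(dur) != 1 || dur <= 0)
      stop("each protocol entry needs a positive duration_s")
    list(profile = prof, duration_s = dur)
  })
  start <- 0
  for (i in seq_along(bouts)) {
    bouts[[i]]$start_s <- start
    bouts[[i]]$end_s <- start + bouts[[i]]$duration_s
    start <- bouts[[i]]$end_s
  }
  bouts
}

is_sedentary <- function(profile) {
  profile$dynamic_amplitude_ms2 == 0 && profile$altitude_rate_m_per_s == 0
}

bout_at <- function(bouts, t_s) {
  ends <- vapply(bouts, `[[`, numeric(1), "end_s")
  idx <- findInterval(t_s, c(0, ends), rightmost.closed = FALSE)
  pmin(pmax(idx, 1L), length(bouts))
}

#' Simulate a multi-sensor recording session
#'
#' Generates irregularly sampled sensor streams for one subject executing an
#' ordered activity protocol, together with ground-truth annotation
#' segments. The accelerometer is the posture's gravity vector plus a
#' harmonic gait waveform at the activity's fundamental frequency scaled to
#' its peak dynamic amplitude, plus Gaussian noise; the magnetometer sees
#' the geomagnetic field in the device frame plus a scaled gait component;
#' the gyroscope carries only the gait component; pressure follows the
#' international barometric formula along the integrated altitude track.
#' When a watch device has dropout enabled, its accelerometer emits no
#' samples during sedentary bouts (the power-saving shutdown that
#' hold-last-value filling repairs downstream).
#'
#' @param protocol list of bouts, each `list(profile =, duration_s =)`;
#'   `profile` may be an [activity_profile()] or a label string.
#' @param devices list of [device_spec()] objects.
#' @param seed integer seed; identical seeds give identical output.
#' @param h0_m baseline altitude of the session, metres.
#' @return a list with `streams` (per device, a named list of
#'   [sensor_stream()]s) and `segments` (per device annotation rows).
#' @export
#' @examples
#' ses <- simulate_session(list(list(profile = "walking", duration_s = 10)),
#'                         devices = list(device_spec("phone")), seed = 1)
#' ses$segments
simulate_session <- function(protocol,
                             devices = list(device_spec("phone"), device_spec("watch")),
                             seed = 1L, h0_m = 50) {
  bouts <- normalize_protocol(protocol)
  total_ms <- 1000 * bouts[[length(bouts)]]$end_s
  withr::with_seed(as.integer(seed), {
    # per-bout orientation azimuth and gait phase (shared across devices so
    # phone and watch see a coherent session)
    nb <- length(bouts)
    azimuths <- runif(nb, 0, 2 * pi)
    phases <- runif(nb, 0, 2 * pi)
    alt <- make_altitude_track(bouts, h0 = h0_m)

    sample_inertial <- function(t_ms, kind, noise_sd) {
      t_s <- t_ms / 1000
      bi <- bout_at(bouts, t_s)
      out <- matrix(0, length(t_s), 3)
      for (i in unique(bi)) {
        sel <- bi == i
        b <- bouts[[i]]
        pv <- posture_vectors(b$profile$gravity_axis_angle_deg, azimuths[i])
        w <- gait_wave(t_s[sel] - b$start_s, b$profile$gait_frequency_hz, phases[i])
        amp <- b$profile$dynamic_amplitude_ms2
        scale <- switch(kind, accelerometer = 1, magnetometer = 0.5, gyroscope = 0.25)
        static <- switch(kind, accelerometer = pv$gravity,
                         magnetometer = pv$bfield, gyroscope = c(0, 0, 0))
        dyn <- outer(w, AXIS_WEIGHTS * amp * scale)
        out[sel, ] <- sweep(dyn, 2, static, `+`)
      }
      out + matrix(rnorm(length(out), 0, noise_sd), nrow(out))
    }

    streams <- list()
    segs <- list()
    for (dev in devices) {
      dstreams <- list()
      for (kind in names(dev$rates_hz)) {
        if (kind %in% c("light", "gps")) next  # generated by simulate_transition_walk
        tt <- jittered_times(total_ms, dev$rates_hz[[kind]], dev$jitter_fraction)
        if (kind == "accelerometer" && dev$watch_dropout) {
          sed <- vapply(bouts, function(b) is_sedentary(b$profile), logical(1))
          keep <- !sed[bout_at(bouts, tt / 1000)]
          tt <- tt[keep]
          if (length(tt) == 0) next
        }
        vals <- switch(kind,
          accelerometer = ,
          magnetometer = ,
          gyroscope = sample_inertial(tt, kind, dev$noise_sd[[kind]]),
          pressure = matrix(altitude_to_pressure(alt(tt / 1000)) +
                              rnorm(length(tt), 0, dev$noise_sd[["pressure"]]), ncol = 1)
        )
        dstreams[[kind]] <- sensor_stream(dev$device, kind, tt, vals)
      }
      streams[[dev$device]] <- dstreams
      segs[[dev$device]] <- activity_segments(
        label = vapply(bouts, function(b) b$profile$label, character(1)),
        start_ms = 1000 * vapply(bouts, `[[`, numeric(1), "start_s"),
        end_ms = 1000 * vapply(bouts, `[[`, numeric(1), "end_s"),
        device = dev$device, accepted = TRUE)
    }
    list(streams = streams, segments = do.call(rbind, unname(segs)))
  })
}

#' Default study-like activity protocol
#'
#' A ten-minute scripted sequence mixing all nine activities with walking
#' over-represented, as in a realistic building-to-building protocol:
#' ambulation dominates, stair and elevator bouts are short.
#'
#' @return a protocol list for [simulate_session()].
#' @export
default_protocol <- function() {
  sched <- list(
    c("walking", 60), c("standing", 60), c("walking", 30), c("sitting", 90),
    c("walking", 30), c("running", 60), c("cycling", 120),
    c("stair_ascent", 30), c("stair_descent", 30),
    c("elevator_ascent", 30), c("elevator_descent", 30), c("walking", 30))
  lapply(sched, function(s) list(profile = s[1], duration_s = as.numeric(s[2])))
}

#' Simulate a cohort of virtual subjects
#'
#' Runs [simulate_session()] once per subject with subject-specific
#' perturbations of the activity profiles (gait frequency +/-5%, dynamic
#' amplitude +/-10%, posture angle +/-3 degrees), emulating between-subject
#' variability while keeping activities separable.
#'
#' @param n_subjects number of virtual subjects.
#' @param protocol shared protocol (see [default_protocol()]).
#' @param devices list of [device_spec()]s.
#' @param seed master seed; per-subject seeds are derived from it.
#' @return list of session objects, one per subject.
#' @export
simulate_cohort <- function(n_subjects = 10, protocol = default_protocol(),
                            devices = list(device_spec("phone"), device_spec("watch")),
                            seed = 1L) {
  stopifnot(n_subjects >= 1)
  sub_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max - 1L, n_subjects))
  lapply(seq_len(n_subjects), function(s) {
    withr::with_seed(sub_seeds[s], {
      proto <- lapply(protocol, function(p) {
        prof <- if (is.character(p$profile)) activity_profile(p$profile) else p$profile
        prof$gait_frequency_hz <- min(7.5, max(0, prof$gait_frequency_hz * rnorm(1, 1, 0.05)))
        prof$dynamic_amplitude_ms2 <- max(0, prof$dynamic_amplitude_ms2 * rnorm(1, 1, 0.1))
        prof$gravity_axis_angle_deg <-
          min(175, max(0, prof$gravity_axis_angle_deg + rnorm(1, 0, 3)))
        list(profile = prof, duration_s = p$duration_s)
      })
      inner <- sample.int(.Machine$integer.max - 1L, 1)
      simulate_session(proto, devices = devices, seed = inner)
    })
  })
}

#' Simulate an indoor-to-outdoor transition walk
#'
#' Generates the phone light stream and GPS fix stream for a walk that
#' starts indoors and moves outdoors. Indoors, GPS fixes are absent when
#' the profile's `gps_visible` is `FALSE` (satellite count collapses to the
#' missing-fix convention downstream) and lux is at indoor levels; outdoors,
#' fixes carry the profile's satellite count and SNR and lux is at daylight
#' level. The truth transition time marks the boundary.
#'
#' @param indoor_s,outdoor_s durations of the indoor and outdoor spans (s).
#' @param indoor_profile,outdoor_profile [activity_profile()]s supplying
#'   `lux_mean`, `gps_visible`, `sat_count_mean`, `sat_snr_mean`.
#' @param device a phone [device_spec()].
#' @param seed integer seed.
#' @return list with `light` and `gps` [sensor_stream()]s, `segments`
#'   (indoor/outdoor annotation rows) and `transition_ms`.
#' @export
simulate_transition_walk <- function(indoor_s = 300, outdoor_s = 300,
                                     indoor_profile = activity_profile("standing", lux_mean = 200),
                                     outdoor_profile = activity_profile("walking"),
                                     device = device_spec("phone"),
                                     seed = 1L) {
  if (indoor_s <= 0 || outdoor_s <= 0) stop("durations must be positive")
  total_ms <- 1000 * (indoor_s + outdoor_s)
  trans_ms <- 1000 * indoor_s
  withr::with_seed(as.integer(seed), {
    # light: lognormal-ish fluctuation about the span mean plus slow flicker
    tt <- jittered_times(total_ms, device$rates_hz[["light"]], device$jitter_fraction)
    mu <- ifelse(tt < trans_ms, indoor_profile$lux_mean, outdoor_profile$lux_mean)
    lux <- pmax(0, mu * (1 + device$noise_sd[["light"]] * rnorm(length(tt))) *
                  (1 + 0.05 * sin(2 * pi * 0.02 * tt / 1000)))
    light <- sensor_stream(device$device, "light", tt, matrix(lux, ncol = 1))

    # one heading for the whole walk (a straight building-to-building
    # route); per-fix scatter only, so no time-locked drift can act as an
    # incidental class cue
    heading <- runif(1, 0, 360)
    gps_fix_block <- function(t_ms, prof) {
      n <- length(t_ms)
      if (n == 0) return(NULL)
      bearing <- (heading + rnorm(n, 0, 8)) %% 360
      cbind(bearing_deg = bearing,
            speed_mps = pmax(0, rnorm(n, 1.4, 0.2)),
            altitude_m = rnorm(n, 50, 3),
            sat_count = pmax(0, round(rnorm(n, prof$sat_count_mean, 1))),
            mean_snr = pmax(0, rnorm(n, prof$sat_snr_mean, 2)))
    }
    gt <- jittered_times(total_ms, device$rates_hz[["gps"]], device$jitter_fraction)
    indoor_t <- gt[gt < trans_ms]
    outdoor_t <- gt[gt >= trans_ms]
    blocks <- list()
    keep_t <- numeric(0)
    if (indoor_profile$gps_visible && length(indoor_t) > 0) {
      blocks <- c(blocks, list(gps_fix_block(indoor_t, indoor_profile)))
      keep_t <- c(keep_t, indoor_t)
    }
    if (outdoor_profile$gps_visible && length(outdoor_t) > 0) {
      blocks <- c(blocks, list(gps_fix_block(outdoor_t, outdoor_profile)))
      keep_t <- c(keep_t, outdoor_t)
    }
    gps <- if (length(keep_t) > 0) {
      sensor_stream(device$device, "gps", keep_t, do.call(rbind, blocks))
    } else {
      structure(list(device = device$device, kind = "gps", t_ms = numeric(0),
                     values = matrix(numeric(0), 0, 5,
                                     dimnames = list(NULL, GPS_CHANNELS)),
                     units = "mixed"), class = "sensor_stream")
    }
    segs <- activity_segments(label = c("indoor", "outdoor"),
                              start_ms = c(0, trans_ms),
                              end_ms = c(trans_ms, total_ms),
                              device = device$device)
    list(light = light, gps = gps, segments = segs, transition_ms = trans_ms)
  })
}
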