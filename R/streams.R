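ACTIVITY_LABELS <- c("walking", "running", "cycling", "standing", "sitting",
                     "elevator_ascent", "elevator_descent",
                     "stair_ascent", "stair_descent")

ENVIRONMENT_LABELS <- c("indoor", "outdoor")

SENSOR_KINDS <- c("accelerometer", "magnetometer", "gyroscope",
                  "pressure", "light", "gps")

GPS_CHANNELS <- c("bearing_deg", "speed_mps", "altitude_m", "sat_count", "mean_snr")

sensor_channels <- function(kind) {
  switch(kind,
    accelerometer = ,
    magnetometer = ,
    gyroscope = c("x", "y", "z"),
    pressure = "hpa",
    light = "lux",
    gps = GPS_CHANNELS,
    stop("unknown sensor kind: ", kind)
  )
}

sensor_units <- function(kind) {
  switch(kind,
    accelerometer = "m/s^2",
    magnetometer = "uT",
    gyroscope = "rad/s",
    pressure = "hPa",
    light = "lux",
    gps = "mixed",
    stop("unknown sensor kind: ", kind)
  )
}

#' Raw sensor stream
#'
#' Irregularly timestamped samples from a single sensor. Timestamps are
#' milliseconds since session start and must be strictly increasing; the
#' channel layout is fixed per sensor kind (x/y/z for inertial sensors,
#' a single channel for pressure and light, and a five-field record for GPS
#' fixes: bearing, speed, altitude, satellite count, mean SNR).
#'
#' @param device `"phone"` or `"watch"`.
#' @param kind one of accelerometer, magnetometer, gyroscope, pressure,
#'   light, gps.
#' @param t_ms numeric vector of timestamps (ms, strictly increasing).
#' @param values numeric matrix, one row per sample, columns per channel.
#' @return an object of class `sensor_stream`.
#' @export
sensor_stream <- function(device, kind, t_ms, values) {
  device <- match.arg(device, c("phone", "watch"))
  kind <- match.arg(kind, SENSOR_KINDS)
  values <- as.matrix(values)
  chan <- sensor_channels(kind)
  if (ncol(values) != length(chan)) {
    stop(sprintf("sensor kind '%s' requires %d channel(s), got %d",
                 kind, length(chan), ncol(values)))
  }
  colnames(values) <- chan
  if (length(t_ms) != nrow(values)) stop("t_ms and values disagree in length")
  if (length(t_ms) > 1) {
    bad <- which(diff(t_ms) <= 0)
    if (length(bad) > 0) {
      stop(sprintf("timestamps not strictly increasing at row %d", bad[1] + 1L))
    }
  }
  structure(list(device = device, kind = kind,
                 t_ms = as.numeric(t_ms), values = values,
                 units = sensor_units(kind)),
            class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %s %s: %d samples, %.1f s span, ~%.1f Hz\n",
              x$device, x$kind, length(x$t_ms),
              diff(range(x$t_ms)) / 1000,
              if (length(x$t_ms) > 1) 1000 / median(diff(x$t_ms)) else NA_real_))
  invisible(x)
}

#' Fixed-rate multi-channel signal
#'
#' @param device,kind as for [sensor_stream()].
#' @param rate_hz fixed sampling rate.
#' @param start_ms timestamp of the first sample (ms).
#' @param values numeric matrix, one row per sample.
#' @return an object of class `uniform_signal`.
#' @export
uniform_signal <- function(device, kind, rate_hz, start_ms, values) {
  values <- as.matrix(values)
  structure(list(device = device, kind = kind, rate_hz = rate_hz,
                 start_ms = start_ms, values = values),
            class = "uniform_signal")
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf("<uniform_signal> %s %s: %d samples @ %g Hz from t=%g ms\n",
              x$device, x$kind, nrow(x$values), x$rate_hz, x$start_ms))
  invisible(x)
}

signal_times <- function(sig) {
  sig$start_ms + (seq_len(nrow(sig$values)) - 1) * 1000 / sig$rate_hz
}

#' Annotated activity segments
#'
#' Builds and validates the segment table: half-open labeled intervals
#' `[start_ms, end_ms)` with a device id and an accepted flag (the
#' programmatic analogue of manual segment validation).
#'
#' @param label activity (or indoor/outdoor) labels.
#' @param start_ms,end_ms interval bounds in ms, `end_ms > start_ms`.
#' @param device device id per segment.
#' @param accepted logical; rejected segments are never windowed.
#' @return a `data.frame` sorted by `start_ms`.
#' @export
activity_segments <- function(label, start_ms, end_ms, device, accepted = TRUE) {
  ok <- label %in% c(ACTIVITY_LABELS, ENVIRONMENT_LABELS)
  if (!all(ok)) stop("unknown activity label: ", paste(unique(label[!ok]), collapse = ", "))
  if (any(end_ms <= start_ms)) stop("segment end_ms must exceed start_ms")
  seg <- data.frame(label = label, start_ms = start_ms, end_ms = end_ms,
                    device = device, accepted = accepted,
                    stringsAsFactors = FALSE)
  seg[order(seg$start_ms), , drop = FALSE]
}
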