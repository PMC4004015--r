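# Zero-phase Butterworth filtering with odd-reflection edge padding. The
# pad length tracks the slowest cutoff (transients of a low-cutoff IIR
# filter extend roughly one cutoff period), capped at the signal length.
butter_filtfilt <- function(x, order, cutoff_hz, rate_hz,
                            type = c("low", "high", "pass")) {
  type <- match.arg(type)
  nyq <- rate_hz / 2
  if (any(cutoff_hz <= 0) || any(cutoff_hz >= nyq))
    stop("filter cutoff must lie strictly between 0 and the Nyquist frequency")
  flt <- signal::butter(order, cutoff_hz / nyq, type = type)
  n <- length(x)
  # center before filtering: the filter state starts at zero, so a large DC
  # offset would otherwise inject an edge transient; the offset is restored
  # through the filter's exact DC gain (1 for low-pass, 0 otherwise)
  mu <- mean(x)
  x <- x - mu
  np <- min(n - 1L, ceiling(2 * rate_hz / min(cutoff_hz)))
  if (np > 0) {
    left <- 2 * x[1] - x[(np + 1):2]
    right <- 2 * x[n] - x[(n - 1):(n - np)]
    xp <- c(left, x, right)
  } else {
    xp <- x
  }
  y <- as.numeric(signal::filter(flt, xp))
  y <- rev(as.numeric(signal::filter(flt, rev(y))))
  y[(np + 1):(np + n)] + if (type == "low") mu else 0
}

filter_signal <- function(sig, order, cutoff_hz, type) {
  vals <- apply(sig$values, 2, butter_filtfilt, order = order,
                cutoff_hz = cutoff_hz, rate_hz = sig$rate_hz, type = type)
  vals <- matrix(vals, nrow = nrow(sig$values),
                 dimnames = list(NULL, colnames(sig$values)))
  uniform_signal(sig$device, sig$kind, sig$rate_hz, sig$start_ms, vals)
}

#' Gravity (static component) low-pass filter
#'
#' Zero-phase Butterworth low-pass at 0.6 Hz isolating the orientation
#' (gravity) component of an inertial signal: DC passes with unit gain,
#' gait-band content above ~2 Hz is strongly attenuated. Applied
#' forward-backward so filtered windows stay aligned with raw time.
#'
#' @param sig a [uniform_signal()] (inertial, typically 100 Hz).
#' @param config a [pipeline_config()].
#' @return filtered [uniform_signal()].
#' @export
gravity_lowpass <- function(sig, config = pipeline_config()) {
  filter_signal(sig, config$filter_order, config$gravity_lowpass_cutoff_hz, "low")
}

#' Gait-band (dynamic component) band-pass filter
#'
#' Zero-phase Butterworth band-pass, 0.6-7.5 Hz: rejects gravity (DC) and
#' high-frequency noise while retaining typical human gait periodicity.
#' Applied to accelerometer, magnetometer and gyroscope alike.
#'
#' @inheritParams gravity_lowpass
#' @return filtered [uniform_signal()].
#' @export
dynamic_bandpass <- function(sig, config = pipeline_config()) {
  filter_signal(sig, config$filter_order, config$bandpass_hz, "pass")
}

#' Pressure detrending high-pass filter
#'
#' Zero-phase Butterworth high-pass at 0.1 Hz removing weather-scale
#' barometric drift while preserving the fast excursions caused by elevator
#' and stair transitions.
#'
#' @param sig a pressure [uniform_signal()] (typically 10 Hz).
#' @inheritParams gravity_lowpass
#' @return filtered [uniform_signal()].
#' @export
pressure_highpass <- function(sig, config = pipeline_config()) {
  filter_signal(sig, config$filter_order, config$pressure_highpass_cutoff_hz, "high")
}
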