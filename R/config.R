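#' Pipeline configuration
#'
#' Bundles every numeric constant used by the resampling, filtering,
#' windowing and modeling stages. Defaults follow standard practice for
#' gait-band inertial processing: inertial streams are resampled to 100 Hz
#' and pressure/light to 10 Hz; the static (gravity) component is isolated
#' with a 0.6 Hz low-pass; the dynamic component with a 0.6-7.5 Hz band-pass
#' (the band retaining typical human gait periodicity); pressure is
#' high-passed at 0.1 Hz to remove weather-scale drift; features are computed
#' on non-overlapping 2 s windows.
#'
#' @param inertial_rate_hz resample rate for accelerometer/magnetometer/gyro.
#' @param pressure_rate_hz resample rate for the barometer.
#' @param light_rate_hz resample rate for the ambient light sensor.
#' @param gravity_lowpass_cutoff_hz low-pass cutoff isolating gravity.
#' @param bandpass_hz length-2 band (low, high) isolating gait dynamics.
#' @param pressure_highpass_cutoff_hz high-pass cutoff detrending pressure.
#' @param light_lowpass_cutoff_hz low-pass cutoff for the smoothed lux track.
#' @param filter_order Butterworth order (applied forward-backward).
#' @param window_s analysis window length in seconds.
#' @param max_gap_ms gaps longer than this are hold-last filled.
#' @param pca_variance cumulative explained-variance target for PCA.
#' @param cv_folds stratified cross-validation folds.
#' @param mlp_maxit training iterations for the multilayer perceptron.
#' @param seed default seed threaded through stochastic stages.
#'
#' @return an object of class `pipeline_config` (a named list).
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$bandpass_hz
pipeline_config <- function(inertial_rate_hz = 100,
                            pressure_rate_hz = 10,
                            light_rate_hz = 10,
                            gravity_lowpass_cutoff_hz = 0.6,
                            bandpass_hz = c(0.6, 7.5),
                            pressure_highpass_cutoff_hz = 0.1,
                            light_lowpass_cutoff_hz = 0.5,
                            filter_order = 4,
                            window_s = 2,
                            max_gap_ms = 2000,
                            pca_variance = 0.95,
                            cv_folds = 10,
                            mlp_maxit = 200,
                            seed = 1L) {
  stopifnot(length(bandpass_hz) == 2)
  if (!(bandpass_hz[1] > 0 && bandpass_hz[1] < bandpass_hz[2] &&
        bandpass_hz[2] < inertial_rate_hz / 2)) {
    stop("bandpass_hz must satisfy 0 < low < high < Nyquist of the inertial rate")
  }
  if (gravity_lowpass_cutoff_hz >= inertial_rate_hz / 2)
    stop("gravity low-pass cutoff must be below the inertial Nyquist frequency")
  if (pressure_highpass_cutoff_hz >= pressure_rate_hz / 2)
    stop("pressure high-pass cutoff must be below the pressure Nyquist frequency")
  structure(list(
    inertial_rate_hz = inertial_rate_hz,
    pressure_rate_hz = pressure_rate_hz,
    light_rate_hz = light_rate_hz,
    gravity_lowpass_cutoff_hz = gravity_lowpass_cutoff_hz,
    bandpass_hz = bandpass_hz,
    pressure_highpass_cutoff_hz = pressure_highpass_cutoff_hz,
    light_lowpass_cutoff_hz = light_lowpass_cutoff_hz,
    filter_order = filter_order,
    window_s = window_s,
    max_gap_ms = max_gap_ms,
    pca_variance = pca_variance,
    cv_folds = cv_folds,
    mlp_maxit = mlp_maxit,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}
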