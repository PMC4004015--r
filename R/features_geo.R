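GEO_FEATURE_NAMES <- c("mean_bearing_deg", "mean_speed_mps", "mean_altitude_m",
                       "mean_sat_count", "mean_sat_snr",
                       "raw_mean_lux", "lowpass_mean_lux", "mean_diff_lux")

GPS_FEATURE_NAMES <- GEO_FEATURE_NAMES[1:5]
LIGHT_FEATURE_NAMES <- GEO_FEATURE_NAMES[6:8]

#' Circular mean of bearings
#'
#' Vector mean of angles in degrees, correct across the 0/360 wrap
#' (e.g. bearings 350 and 10 average to 0, not 180).
#'
#' @param deg bearings in degrees.
#' @return mean bearing in `[0, 360)`.
#' @export
circular_mean_deg <- function(deg) {
  r <- deg * pi / 180
  out <- (atan2(mean(sin(r)), mean(cos(r))) * 180 / pi) %% 360
  if (out >= 360 - 1e-9) 0 else out  # tiny negative angles must wrap to 0, not 360
}

#' GPS features for one window
#'
#' Aggregates the raw fixes falling in the window (fixes are never
#' interpolated): circular mean bearing, arithmetic mean speed, altitude,
#' satellite count and SNR. An empty fix list — the indoor condition —
#' yields satellite count 0 and SNR 0 (absence encoded as signal, the
#' discriminative indoor cue) with the remaining fields missing.
#'
#' @param gps a GPS [sensor_stream()].
#' @param start_ms,end_ms window interval, half-open.
#' @return named numeric vector of the five GPS features.
#' @export
gps_features <- function(gps, start_ms, end_ms) {
  sel <- gps$t_ms >= start_ms & gps$t_ms < end_ms
  if (!any(sel)) {
    return(c(mean_bearing_deg = NA_real_, mean_speed_mps = NA_real_,
             mean_altitude_m = NA_real_, mean_sat_count = 0, mean_sat_snr = 0))
  }
  v <- gps$values[sel, , drop = FALSE]
  c(mean_bearing_deg = circular_mean_deg(v[, "bearing_deg"]),
    mean_speed_mps = mean(v[, "speed_mps"]),
    mean_altitude_m = mean(v[, "altitude_m"]),
    mean_sat_count = mean(v[, "sat_count"]),
    mean_sat_snr = mean(v[, "mean_snr"]))
}

#' Light features for one window
#'
#' Mean of the raw lux slice, mean of the low-passed lux slice, and the
#' mean first difference of the raw slice (a linear ramp of slope `s` per
#' sample gives exactly `s`).
#'
#' @param raw_lux raw lux values in the window.
#' @param lowpass_lux low-passed lux values in the window.
#' @return named numeric vector of the three light features.
#' @export
light_features <- function(raw_lux, lowpass_lux) {
  c(raw_mean_lux = mean(raw_lux),
    lowpass_mean_lux = mean(lowpass_lux),
    mean_diff_lux = if (length(raw_lux) > 1) mean(diff(raw_lux)) else 0)
}

#' Build the windowed GPS + light feature table
#'
#' Resamples light to 10 Hz, low-passes it at the configured cutoff, cuts
#' the labelled indoor/outdoor segments into windows and computes the eight
#' geo features per window.
#'
#' @param walk output of [simulate_transition_walk()], or any list with
#'   `light`, `gps` and indoor/outdoor `segments`.
#' @param config a [pipeline_config()].
#' @return data frame with `label` plus the eight feature columns.
#' @export
geo_feature_table <- function(walk, config = pipeline_config()) {
  rows <- list()
  segs <- walk$segments
  for (i in seq_len(nrow(segs))) {
    # resample and low-pass within each annotated span: an indoor/outdoor
    # transition is an instantaneous lux step (a doorway), so neither the
    # interpolator nor the smoothing filter may bridge the boundary
    sel <- walk$light$t_ms >= segs$start_ms[i] & walk$light$t_ms < segs$end_ms[i]
    if (sum(sel) < 2) next
    sub <- sensor_stream(walk$light$device, "light",
                         walk$light$t_ms[sel],
                         walk$light$values[sel, , drop = FALSE])
    light_u <- resample_linear(sub, config$light_rate_hz)
    light_lp <- filter_signal(light_u, config$filter_order,
                              config$light_lowpass_cutoff_hz, "low")
    span <- segs[i, , drop = FALSE]
    span$start_ms <- light_u$start_ms
    span$end_ms <- max(signal_times(light_u))
    wins <- extract_windows(span, list(light = light_u, light_lp = light_lp),
                            config$window_s, segment_id = i)
    for (w in wins) {
      lf <- light_features(as.numeric(w$slices$light), as.numeric(w$slices$light_lp))
      gf <- gps_features(walk$gps, w$start_ms, w$start_ms + 1000 * config$window_s)
      rows[[length(rows) + 1L]] <- data.frame(label = w$label, as.list(c(gf, lf)),
                                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Indoor/outdoor detection from GPS, light, or both
#'
#' Evaluates a classifier on the geo feature table restricted to the GPS
#' features only, the light features only, and the fused set, under the
#' same stratified cross-validation protocol as the activity models.
#'
#' @param geo_table output of [geo_feature_table()] (possibly several
#'   walks row-bound together).
#' @param classifier one of `"c45"`, `"cart"`, `"nb"`, `"mlp"`, `"svm"`.
#' @param folds cross-validation folds.
#' @param seed integer seed.
#' @return named list of [train_eval()] reports: `gps`, `light`, `fused`.
#' @export
detect_environment <- function(geo_table, classifier = "nb", folds = 10, seed = 1L) {
  if (length(unique(geo_table$label)) < 2)
    stop("geo table must contain both indoor and outdoor windows")
  subsets <- list(gps = GPS_FEATURE_NAMES, light = LIGHT_FEATURE_NAMES,
                  fused = GEO_FEATURE_NAMES)
  lapply(subsets, function(cols) {
    tab <- geo_table[, c("label", cols), drop = FALSE]
    tab$label <- factor(tab$label, levels = ENVIRONMENT_LABELS)
    train_eval(tab, classifier = classifier, folds = folds, seed = seed)
  })
}
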