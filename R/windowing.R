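#' Cut an accepted segment into fixed-length windows
#'
#' Non-overlapping, contiguous windows of exactly `window_s` seconds,
#' aligned to the segment start; a trailing remainder shorter than one
#' window is discarded. Each window carries a slice of every supplied
#' signal plus the segment label. Rejected segments yield no windows; a
#' segment shorter than one window yields an empty list.
#'
#' @param segment one row of a segment table (see [activity_segments()]).
#' @param signals named list of [uniform_signal()]s that must cover the
#'   segment span.
#' @param window_s window length, seconds.
#' @param segment_id identifier stored in each window's provenance.
#' @return list of windows; each is a list with `label`, `start_ms`,
#'   `index`, `segment_id` and `slices` (named list of matrices with the
#'   source signal's `rate_hz` attached).
#' @export
extract_windows <- function(segment, signals, window_s = 2, segment_id = 1L) {
  if (!isTRUE(as.logical(segment$accepted))) return(list())
  span_ms <- segment$end_ms - segment$start_ms
  n_win <- floor(span_ms / (1000 * window_s))
  if (n_win < 1) return(list())
  for (nm in names(signals)) {
    sig <- signals[[nm]]
    t_end <- sig$start_ms + (nrow(sig$values) - 1) * 1000 / sig$rate_hz
    if (sig$start_ms > segment$start_ms + 1e-6 || t_end < segment$end_ms - 1000 * window_s) {
      stop(sprintf("signal '%s' does not cover segment [%g, %g) ms",
                   nm, segment$start_ms, segment$end_ms), call. = FALSE)
    }
  }
  lapply(seq_len(n_win), function(k) {
    w0 <- segment$start_ms + (k - 1) * 1000 * window_s
    slices <- lapply(signals, function(sig) {
      ns <- round(window_s * sig$rate_hz)
      i0 <- round((w0 - sig$start_ms) * sig$rate_hz / 1000) + 1L
      i1 <- i0 + ns - 1L
      if (i0 < 1L || i1 > nrow(sig$values)) return(NULL)
      m <- sig$values[i0:i1, , drop = FALSE]
      attr(m, "rate_hz") <- sig$rate_hz
      m
    })
    if (any(vapply(slices, is.null, logical(1)))) return(NULL)
    list(label = segment$label, start_ms = w0, index = k,
         segment_id = segment_id, slices = slices)
  }) -> wins
  wins[!vapply(wins, is.null, logical(1))]
}
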