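#' Write a recording to a directory
#'
#' One CSV per sensor stream, named `<device>_<kind>.csv` with header
#' `t_ms,<channel names>`, plus `segments.csv` with columns
#' `label,start_ms,end_ms,device,accepted`.
#'
#' @param session a list with `streams` (list per device of
#'   [sensor_stream()]s, or a flat list of streams) and `segments`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  streams <- session$streams
  if (inherits(streams, "sensor_stream")) streams <- list(streams)
  flat <- list()
  for (s in streams) {
    if (inherits(s, "sensor_stream")) flat <- c(flat, list(s))
    else flat <- c(flat, unname(s))
  }
  for (s in flat) {
    df <- data.frame(t_ms = s$t_ms, s$values, check.names = FALSE)
    write.csv(df, file.path(dir, paste0(s$device, "_", s$kind, ".csv")),
              row.names = FALSE)
  }
  write.csv(session$segments, file.path(dir, "segments.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a recording directory
#'
#' Inverse of [write_recording()]: parses every `<device>_<kind>.csv` into a
#' validated [sensor_stream()] (non-monotone timestamps are rejected with
#' the offending row) and `segments.csv` into a segment table sorted by
#' start time. A missing or empty segments file yields zero segments.
#'
#' @param dir recording directory.
#' @return list with `streams` (per device) and `segments`.
#' @export
read_recording <- function(dir) {
  if (!dir.exists(dir)) stop("no such recording directory: ", dir)
  files <- list.files(dir, pattern = "^(phone|watch)_[a-z]+\\.csv$")
  streams <- list()
  for (f in files) {
    parts <- strsplit(sub("\\.csv$", "", f), "_", fixed = TRUE)[[1]]
    device <- parts[1]
    kind <- paste(parts[-1], collapse = "_")
    if (!kind %in% SENSOR_KINDS) stop("unknown sensor kind in file: ", f)
    df <- read.csv(file.path(dir, f), check.names = FALSE)
    streams[[device]][[kind]] <-
      sensor_stream(device, kind, df$t_ms,
                    as.matrix(df[, setdiff(names(df), "t_ms"), drop = FALSE]))
  }
  segf <- file.path(dir, "segments.csv")
  segments <- if (file.exists(segf)) {
    sdf <- read.csv(segf)
    if (nrow(sdf) == 0) sdf
    else activity_segments(sdf$label, sdf$start_ms, sdf$end_ms, sdf$device,
                           as.logical(sdf$accepted))
  } else {
    data.frame(label = character(0), start_ms = numeric(0), end_ms = numeric(0),
               device = character(0), accepted = logical(0))
  }
  list(streams = streams, segments = segments)
}

#' Resample an irregular stream to a fixed rate
#'
#' Linear interpolation onto a uniform grid spanning the raw time range
#' `[first, last]`; values are never extrapolated beyond the raw span.
#' GPS fixes are never interpolated (they are aggregated per window by the
#' geo feature stage).
#'
#' @param stream a [sensor_stream()] with at least two samples.
#' @param target_rate_hz output rate (Hz).
#' @return a [uniform_signal()].
#' @export
resample_linear <- function(stream, target_rate_hz) {
  stopifnot(inherits(stream, "sensor_stream"))
  if (stream$kind == "gps") stop("GPS fixes are not interpolated")
  if (target_rate_hz <= 0) stop("target rate must be positive")
  if (length(stream$t_ms) < 2) stop("need at least 2 samples to resample")
  grid <- seq(stream$t_ms[1], stream$t_ms[length(stream$t_ms)],
              by = 1000 / target_rate_hz)
  out <- vapply(seq_len(ncol(stream$values)), function(j) {
    approx(stream$t_ms, stream$values[, j], xout = grid, method = "linear")$y
  }, numeric(length(grid)))
  out <- matrix(out, nrow = length(grid),
                dimnames = list(NULL, colnames(stream$values)))
  uniform_signal(stream$device, stream$kind, target_rate_hz, grid[1], out)
}

#' Hold-last-value gap filling
#'
#' Gaps longer than `max_gap_ms` (a sensor power-down, typically the watch
#' accelerometer during a sedentary bout) are filled at the stream's nominal
#' rate with the last observed value; shorter gaps are left to linear
#' interpolation. Inserted samples are flagged in the returned stream's
#' `synthetic` element.
#'
#' @param stream a non-empty [sensor_stream()].
#' @param max_gap_ms gap threshold (default one window, 2000 ms).
#' @param nominal_rate_hz fill rate; defaults to the median observed rate.
#' @return a [sensor_stream()] with logical element `synthetic`.
#' @export
fill_hold_last <- function(stream, max_gap_ms = 2000, nominal_rate_hz = NULL) {
  stopifnot(inherits(stream, "sensor_stream"))
  n <- length(stream$t_ms)
  if (n == 0) stop("cannot fill an empty stream")
  if (n == 1) {
    stream$synthetic <- FALSE
    return(stream)
  }
  dts <- diff(stream$t_ms)
  if (is.null(nominal_rate_hz)) nominal_rate_hz <- 1000 / median(dts)
  step <- 1000 / nominal_rate_hz
  gaps <- which(dts > max_gap_ms)
  if (length(gaps) == 0) {
    stream$synthetic <- rep(FALSE, n)
    return(stream)
  }
  t_new <- list()
  v_new <- list()
  flag <- list()
  prev <- 1L
  for (g in gaps) {
    idx <- prev:g
    t_new <- c(t_new, list(stream$t_ms[idx]))
    v_new <- c(v_new, list(stream$values[idx, , drop = FALSE]))
    flag <- c(flag, list(rep(FALSE, length(idx))))
    fill_t <- seq(stream$t_ms[g] + step, stream$t_ms[g + 1] - step / 2, by = step)
    if (length(fill_t) > 0) {
      t_new <- c(t_new, list(fill_t))
      v_new <- c(v_new, list(matrix(rep(stream$values[g, ], each = length(fill_t)),
                                    nrow = length(fill_t))))
      flag <- c(flag, list(rep(TRUE, length(fill_t))))
    }
    prev <- g + 1L
  }
  idx <- prev:n
  t_new <- c(t_new, list(stream$t_ms[idx]))
  v_new <- c(v_new, list(stream$values[idx, , drop = FALSE]))
  flag <- c(flag, list(rep(FALSE, length(idx))))
  out <- sensor_stream(stream$device, stream$kind, unlist(t_new),
                       do.call(rbind, v_new))
  out$synthetic <- unlist(flag)
  out
}
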