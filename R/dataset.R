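#' Assemble a labeled feature table
#'
#' Restricts extracted feature vectors to one device's schema and one
#' sensor subset (columns attributed to that sensor in the phone feature
#' table; the watch supports only its accelerometer set). Rows are ordered
#' deterministically by segment then window index; the label becomes a
#' factor over the nine activities.
#'
#' @param features feature data frame from [extract_features()] (`$phone`
#'   or `$watch`).
#' @param device `"phone"` or `"watch"`.
#' @param subset for the phone one of `"fused"`, `"accelerometer"`,
#'   `"magnetometer"`, `"gyro"`, `"pressure"`; for the watch
#'   `"accelerometer"` (the full watch schema).
#' @return a data frame with `label` first, then the subset's feature
#'   columns; attributes `device` and `subset`.
#' @export
build_dataset <- function(features, device = c("phone", "watch"), subset = "fused") {
  device <- match.arg(device)
  schema <- feature_schema(device)
  if (!all(schema %in% names(features)))
    stop("feature table does not carry the full ", device, " schema")
  cols <- if (device == "phone") {
    feature_sensor_columns(subset)
  } else {
    if (!subset %in% c("accelerometer", "fused"))
      stop("watch supports only the accelerometer subset")
    schema
  }
  ord <- order(features$segment_id, features$window_idx)
  out <- data.frame(label = factor(features$label[ord], levels = ACTIVITY_LABELS),
                    features[ord, cols, drop = FALSE],
                    check.names = FALSE, row.names = NULL)
  attr(out, "device") <- device
  attr(out, "subset") <- subset
  out
}

#' Balance a dataset by subsampling
#'
#' Downsamples every class without replacement to the minimum class count,
#' so each of k classes can contribute at most 100/k percent to the overall
#' true-positive rate. Deterministic under the seed.
#'
#' @param table a feature table with a factor `label` column.
#' @param seed integer seed.
#' @return a balanced table (row order: by class, then original order).
#' @export
balance_dataset <- function(table, seed = 1L) {
  present <- table(droplevels(table$label))
  zero <- setdiff(levels(table$label), names(present))
  if (length(zero) > 0)
    stop("class with zero instances: ", paste(zero, collapse = ", "))
  m <- min(present)
  keep <- withr::with_seed(as.integer(seed), {
    unlist(lapply(levels(table$label), function(cl) {
      idx <- which(table$label == cl)
      sort(sample(idx, m))
    }))
  })
  out <- table[keep, , drop = FALSE]
  attr(out, "device") <- attr(table, "device")
  attr(out, "subset") <- attr(table, "subset")
  attr(out, "balance_seed") <- as.integer(seed)
  row.names(out) <- NULL
  out
}

#' Write / read a feature table
#'
#' CSV via base R; ARFF via the `foreign` package, with the class attribute
#' declared nominal over its factor levels (all nine activities even when
#' some are absent from the data) and missing cells encoded as `?`.
#'
#' @param table a feature table (factor `label` column).
#' @param path output file.
#' @param format `"csv"` or `"arff"`.
#' @return `path`, invisibly (for `write_table`); the table (for
#'   `read_table`).
#' @export
write_table <- function(table, path, format = c("csv", "arff")) {
  format <- match.arg(format)
  if (format == "csv") {
    write.csv(table, path, row.names = FALSE)
  } else {
    foreign::write.arff(table, path)
  }
  invisible(path)
}

#' @rdname write_table
#' @param labels factor levels to restore for the `label` column when
#'   reading CSV (ARFF carries its own nominal declaration).
#' @export
read_table <- function(path, format = c("csv", "arff"), labels = ACTIVITY_LABELS) {
  format <- match.arg(format)
  if (format == "csv") {
    out <- read.csv(path, check.names = FALSE)
    out$label <- factor(out$label, levels = labels)
    out
  } else {
    foreign::read.arff(path)
  }
}
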