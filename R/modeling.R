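CLASSIFIER_IDS <- c("c45", "cart", "nb", "mlp", "svm")

# Stratified fold assignment: shuffle within class, deal folds round-robin.
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Training-fold median imputation (columns that are all-NA fall back to 0).
impute_medians <- function(train, test) {
  for (j in names(train)) {
    if (!is.numeric(train[[j]])) next
    if (anyNA(train[[j]]) || anyNA(test[[j]])) {
      med <- median(train[[j]], na.rm = TRUE)
      if (!is.finite(med)) med <- 0
      train[[j]][is.na(train[[j]])] <- med
      test[[j]][is.na(test[[j]])] <- med
    }
  }
  list(train = train, test = test)
}

# Standardization fit on the training fold only; zero-variance guard.
fit_scaler <- function(train) {
  num <- vapply(train, is.numeric, logical(1))
  mu <- vapply(train[num], mean, numeric(1))
  sig <- vapply(train[num], sd, numeric(1))
  sig[!is.finite(sig) | sig < 1e-12] <- 1
  list(cols = names(train)[num], mu = mu, sd = sig)
}

apply_scaler <- function(df, sc) {
  for (j in sc$cols) df[[j]] <- (df[[j]] - sc$mu[[j]]) / sc$sd[[j]]
  df
}

fit_predict <- function(classifier, train, test, seed, mlp_maxit = 200) {
  if (classifier %in% c("mlp", "svm")) {
    sc <- fit_scaler(train[, setdiff(names(train), "label"), drop = FALSE])
    train[sc$cols] <- apply_scaler(train[sc$cols], sc)[sc$cols]
    test[sc$cols] <- apply_scaler(test[sc$cols], sc)[sc$cols]
  }
  switch(classifier,
    c45 = {
      fit <- rpart::rpart(label ~ ., data = train, method = "class",
                          parms = list(split = "information"),
                          control = rpart::rpart.control(cp = 0.003, minsplit = 10,
                                                         minbucket = 5, xval = 0))
      predict(fit, test, type = "class")
    },
    cart = {
      fit <- rpart::rpart(label ~ ., data = train, method = "class",
                          parms = list(split = "gini"),
                          control = rpart::rpart.control(cp = 0.003, minsplit = 10,
                                                         minbucket = 5, xval = 0))
      predict(fit, test, type = "class")
    },
    nb = {
      fit <- e1071::naiveBayes(label ~ ., data = train)
      # guard against degenerate within-class parameters: a zero variance
      # (e.g. satellite count exactly zero indoors) makes the Gaussian
      # density undefined, and a class that never observes a feature (all
      # NA) gets NaN moments — make that feature uninformative for it
      fit$tables <- lapply(fit$tables, function(tb) {
        if (is.matrix(tb) && ncol(tb) == 2) {
          bad <- !is.finite(tb[, 1])
          tb[bad, 1] <- 0
          tb[bad, 2] <- 1e6
          tb[, 2] <- pmax(tb[, 2], 1e-2)
        }
        tb
      })
      # keep genuinely tiny densities tiny: the default clipping floor
      # (1e-3) can rank an impossible class above a diffuse correct one
      predict(fit, test, type = "class", eps = 0, threshold = 1e-300)
    },
    mlp = {
      p <- ncol(train) - 1L
      size <- max(2L, ceiling(p / 2))
      fit <- withr::with_seed(as.integer(seed),
        nnet::nnet(label ~ ., data = train, size = size, decay = 1e-3,
                   maxit = mlp_maxit, MaxNWts = 20000, trace = FALSE))
      cls <- predict(fit, test, type = "class")
      factor(cls, levels = levels(train$label))
    },
    svm = {
      fit <- e1071::svm(label ~ ., data = train, kernel = "radial", scale = FALSE)
      predict(fit, test)
    },
    stop("unknown classifier id: ", classifier)
  )
}

#' Stratified cross-validated classifier evaluation
#'
#' Trains and evaluates one of five standard classifiers — C4.5-style
#' (information-gain) and CART-style (Gini) decision trees, Gaussian naive
#' Bayes, a single-hidden-layer perceptron (hidden size = half the feature
#' count), and an RBF-kernel SVM — under stratified k-fold cross-validation.
#' Features are standardized for the perceptron and SVM, with scaling and
#' median imputation fit on training folds only. The report aggregates
#' out-of-fold predictions into a confusion matrix; the overall
#' true-positive rate is `100 * trace(confusion) / sum(confusion)`.
#'
#' @param table feature table with factor `label` first (absent levels are
#'   dropped).
#' @param classifier one of `"c45"`, `"cart"`, `"nb"`, `"mlp"`, `"svm"`.
#' @param folds number of folds; every class needs at least this many
#'   instances.
#' @param seed integer seed (fold assignment and perceptron init).
#' @param mlp_maxit perceptron training iterations.
#' @return an object of class `eval_report`: classifier id, `overall_tp_pct`,
#'   `per_class_tp_pct`, `confusion`, `folds`, `seed`, `n`.
#' @export
train_eval <- function(table, classifier = "cart", folds = 10, seed = 1L,
                       mlp_maxit = 200) {
  classifier <- match.arg(classifier, CLASSIFIER_IDS)
  stopifnot(is.factor(table$label))
  table$label <- droplevels(table$label)
  counts <- table(table$label)
  small <- names(counts)[counts < folds]
  if (length(small) > 0)
    stop("class with fewer instances than folds: ", paste(small, collapse = ", "))
  fold_id <- stratified_folds(table$label, folds, seed)
  pred <- factor(rep(NA_character_, nrow(table)), levels = levels(table$label))
  for (f in seq_len(folds)) {
    tr <- table[fold_id != f, , drop = FALSE]
    te <- table[fold_id == f, , drop = FALSE]
    # trees and naive Bayes handle missing values natively (and missingness
    # is itself informative, e.g. absent GPS fixes indoors); the perceptron
    # and SVM need complete numeric input
    imp <- if (classifier %in% c("mlp", "svm")) impute_medians(tr, te)
           else list(train = tr, test = te)
    pred[fold_id == f] <- fit_predict(classifier, imp$train, imp$test,
                                      seed = as.integer(seed) + f,
                                      mlp_maxit = mlp_maxit)
  }
  confusion <- table(truth = table$label, predicted = pred)
  overall <- 100 * sum(diag(confusion)) / sum(confusion)
  per_class <- 100 * diag(confusion) / pmax(rowSums(confusion), 1)
  structure(list(classifier = classifier, overall_tp_pct = overall,
                 per_class_tp_pct = per_class, confusion = confusion,
                 folds = folds, seed = as.integer(seed), n = nrow(table)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s: overall TP %.2f%% (%d instances, %d-fold CV)\n",
              x$classifier, x$overall_tp_pct, x$n, x$folds))
  invisible(x)
}

#' PCA reduction to a target explained variance
#'
#' Standardizes the numeric columns (zero mean, unit variance; constant
#' columns are dropped), decomposes, and keeps the smallest number of
#' components whose cumulative explained variance reaches the target.
#'
#' @param table feature table with factor `label` first.
#' @param variance_target cumulative explained-variance threshold.
#' @return list with `table` (label + k component scores), `loadings`
#'   (orthonormal rotation, p x k), `k`, and `explained` (cumulative
#'   variance fractions).
#' @export
pca_reduce <- function(table, variance_target = 0.95) {
  num <- table[, setdiff(names(table), "label"), drop = FALSE]
  if (nrow(num) < 2) stop("PCA requires at least two instances")
  sds <- vapply(num, sd, numeric(1))
  keep <- is.finite(sds) & sds > 1e-12
  if (!any(keep)) stop("table has no variance to decompose")
  num <- num[, keep, drop = FALSE]
  pc <- prcomp(num, center = TRUE, scale. = TRUE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(cum >= variance_target)[1]
  out <- data.frame(label = table$label, pc$x[, seq_len(k), drop = FALSE])
  list(table = out, loadings = pc$rotation[, seq_len(k), drop = FALSE],
       k = k, explained = cum)
}

#' Run the full device x subset x balance x classifier matrix
#'
#' One evaluation per combination: phone (fused, accelerometer,
#' magnetometer, gyro, pressure) and watch (accelerometer), each balanced
#' and unbalanced, for every requested classifier, plus PCA-reduced
#' variants of the fused phone and watch sets.
#'
#' @param phone_features,watch_features feature data frames from
#'   [extract_features()] (either may be `NULL`).
#' @param classifiers classifier ids to run.
#' @param config a [pipeline_config()].
#' @param with_pca also evaluate PCA-reduced fused sets.
#' @return data frame: one row per evaluation with descriptor columns and
#'   `overall_tp_pct`.
#' @export
run_experiment_matrix <- function(phone_features, watch_features = NULL,
                                  classifiers = CLASSIFIER_IDS,
                                  config = pipeline_config(),
                                  with_pca = TRUE) {
  rows <- list()
  add <- function(device, subset, balanced, pca, classifier, report, k = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      device = device, subset = subset, balanced = balanced, pca = pca,
      classifier = classifier, overall_tp_pct = report$overall_tp_pct,
      n_instances = report$n, pca_k = k, seed = config$seed,
      stringsAsFactors = FALSE)
  }
  run_block <- function(features, device, subsets) {
    for (subset in subsets) {
      base_tab <- build_dataset(features, device, subset)
      for (balanced in c(FALSE, TRUE)) {
        tab <- if (balanced) balance_dataset(base_tab, config$seed) else base_tab
        variants <- list(list(pca = FALSE, tab = tab, k = NA_integer_))
        if (with_pca && subset == "fused") {
          red <- pca_reduce(tab, config$pca_variance)
          variants <- c(variants, list(list(pca = TRUE, tab = red$table, k = red$k)))
        }
        for (v in variants) {
          for (cl in classifiers) {
            rep <- train_eval(v$tab, cl, folds = config$cv_folds,
                              seed = config$seed, mlp_maxit = config$mlp_maxit)
            add(device, subset, balanced, v$pca, cl, rep, v$k)
          }
        }
      }
    }
  }
  if (!is.null(phone_features))
    run_block(phone_features, "phone",
              c("fused", "accelerometer", "magnetometer", "gyro", "pressure"))
  if (!is.null(watch_features)) {
    # the watch's single subset is its full accelerometry schema; PCA runs on it
    wf <- watch_features
    base_tab <- build_dataset(wf, "watch", "accelerometer")
    for (balanced in c(FALSE, TRUE)) {
      tab <- if (balanced) balance_dataset(base_tab, config$seed) else base_tab
      variants <- list(list(pca = FALSE, tab = tab, k = NA_integer_))
      if (with_pca) {
        red <- pca_reduce(tab, config$pca_variance)
        variants <- c(variants, list(list(pca = TRUE, tab = red$table, k = red$k)))
      }
      for (v in variants) {
        for (cl in classifiers) {
          rep <- train_eval(v$tab, cl, folds = config$cv_folds,
                            seed = config$seed, mlp_maxit = config$mlp_maxit)
          add("watch", "accelerometer", balanced, v$pca, cl, rep, v$k)
        }
      }
    }
  }
  do.call(rbind, rows)
}
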