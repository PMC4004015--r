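two_blob_table <- function(n = 60, gap = 10, seed = 5) {
  withr::with_seed(seed, {
    data.frame(
      label = factor(rep(c("walking", "sitting"), each = n),
                     levels = c("walking", "sitting")),
      f1 = c(rnorm(n, 0), rnorm(n, gap)),
      f2 = c(rnorm(n, 0), rnorm(n, gap)))
  })
}

test_that("perfectly separated classes are classified perfectly by every model", {
  tab <- two_blob_table()
  for (cl in c("c45", "cart", "nb", "mlp", "svm")) {
    rep <- train_eval(tab, cl, folds = 5, seed = 2)
    expect_equal(rep$overall_tp_pct, 100, label = cl)
  }
})

test_that("evaluation reports are internally consistent and deterministic", {
  fx <- small_cohort_features()
  tab <- build_dataset(fx$phone, "phone", "accelerometer")
  rep <- train_eval(tab, "cart", folds = 10, seed = 4)
  # confusion row sums equal per-class instance counts
  expect_equal(as.integer(rowSums(rep$confusion)),
               as.integer(table(tab$label)[rownames(rep$confusion)]))
  expect_equal(rep$overall_tp_pct, 100 * sum(diag(rep$confusion)) / sum(rep$confusion))
  expect_true(all(rep$per_class_tp_pct >= 0 & rep$per_class_tp_pct <= 100))
  expect_identical(train_eval(tab, "cart", folds = 10, seed = 4)$confusion, rep$confusion)

  small <- tab[c(which(tab$label == "walking"), which(tab$label == "running")[1:5]), ]
  expect_error(train_eval(small, "cart", folds = 10), "running")
})

test_that("permuted labels drop a balanced problem to chance level", {
  fx <- small_cohort_features()
  tab <- balance_dataset(build_dataset(fx$phone, "phone", "fused"), seed = 3)
  perm <- tab
  perm$label <- withr::with_seed(17, sample(perm$label))
  rep <- train_eval(perm, "cart", folds = 10, seed = 6)
  expect_lt(abs(rep$overall_tp_pct - 100 / 9), 6)
})

test_that("PCA keeps the minimal component count reaching the variance target", {
  # rank-one structure: everything explained by one component
  z <- withr::with_seed(8, rnorm(200))
  rank1 <- data.frame(label = factor(rep("walking", 200)),
                      a = 2 * z, b = -z, c = 0.5 * z + 1)
  expect_equal(pca_reduce(rank1, 0.95)$k, 1)

  # isotropic noise: components share variance equally, so 95% needs all 10
  iso <- withr::with_seed(9, as.data.frame(matrix(rnorm(2000 * 10), ncol = 10)))
  iso$label <- factor(rep("walking", 2000))
  expect_equal(pca_reduce(iso, 0.95)$k, 10)

  fx <- small_cohort_features()
  tab <- build_dataset(fx$phone, "phone", "fused")
  red <- pca_reduce(tab, 0.95)
  expect_gte(red$explained[red$k], 0.95)
  expect_lt(red$explained[red$k - 1], 0.95)
  expect_equal(ncol(red$table) - 1, red$k)
  # loadings are orthonormal
  expect_equal(unname(crossprod(red$loadings)), diag(red$k), tolerance = 1e-8)

  flat <- data.frame(label = factor(rep("walking", 5)), a = rep(1, 5))
  expect_error(pca_reduce(flat), "no variance")
})

test_that("the experiment matrix enumerates device x subset x balance x classifier", {
  fx <- small_cohort_features()
  cfg <- pipeline_config(cv_folds = 5)
  res <- run_experiment_matrix(fx$phone, fx$watch, classifiers = c("c45", "nb"),
                               config = cfg)
  # phone: 5 subsets x 2 balance x 2 classifiers + fused pca variants (2x2)
  # watch: 1 subset x 2 balance x 2 classifiers + pca variants (2x2)
  expect_equal(sum(res$device == "phone" & !res$pca), 20)
  expect_equal(sum(res$device == "phone" & res$pca), 4)
  expect_equal(sum(res$device == "watch"), 8)
  expect_true(all(res$overall_tp_pct >= 0 & res$overall_tp_pct <= 100))
  res2 <- run_experiment_matrix(fx$phone, fx$watch, classifiers = c("c45", "nb"),
                                config = cfg)
  expect_identical(res, res2)
})
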