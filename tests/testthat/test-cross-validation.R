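test_that("folds are disjoint, exhaustive, balanced and stratified", {
  f <- make_folds(rep(c(1, 0), 5), k = 5, seed = 1)
  expect_equal(sort(unique(f$fold)), 1:5)
  expect_equal(as.vector(table(f$fold)), rep(2L, 5))
  expect_equal(length(f$fold), 10L)

  # 6 positives / 4 negatives over 5 folds: every fold gets >= 1 positive
  labels <- c(rep(1, 6), rep(0, 4))
  f <- make_folds(labels, k = 5, seed = 2)
  pos_per_fold <- tapply(labels, f$fold, sum)
  expect_true(all(pos_per_fold >= 1))

  # label ratio per fold within one item per class of the global ratio
  set.seed(3)
  labels <- rbinom(237, 1, 0.38)
  f <- make_folds(labels, k = 5, seed = 4)
  for (cls in 0:1) {
    per_fold <- tapply(labels == cls, f$fold, sum)
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  sizes <- table(f$fold)
  expect_lte(max(sizes) - min(sizes), 1)

  expect_identical(make_folds(labels, seed = 7), make_folds(labels, seed = 7))
  expect_error(make_folds(c(1, 0, 1), k = 5), "at least")
})

# stubs: the first pixel of each patch encodes its label, so a scorer can
# "cheat" perfectly without access to y
label_coded_data <- function(n = 30) {
  labels <- rep(c(1L, 0L), length.out = n)
  x <- matrix(runif(16 * n), 16, n)
  x[1, ] <- labels
  list(x = x, labels = labels)
}

test_that("cross-validation scores every patch exactly once, without leakage", {
  d <- label_coded_data(32)
  seen_train <- list()
  cv <- run_cv(NULL, d$x, d$labels, train_config(seed = 5),
               fit_fun = function(x, y, fold) {
                 seen_train[[fold]] <<- x[2, ]   # fingerprint of training rows
                 "stub"
               },
               score_fun = function(fit, x_test) x_test[1, ])
  expect_equal(nrow(cv$predictions), 32L)
  expect_false(anyNA(cv$predictions$score))
  expect_equal(sort(cv$predictions$index), 1:32)
  # no train/test overlap in any fold
  for (fold in 1:5) {
    test_rows <- d$x[2, cv$predictions$fold == fold]
    expect_length(intersect(test_rows, seen_train[[fold]]), 0)
  }
})

test_that("a perfect scorer yields accuracy and AUC of 1 in every fold", {
  d <- label_coded_data(40)
  cv <- run_cv(NULL, d$x, d$labels, train_config(seed = 6),
               fit_fun = function(x, y, fold) "stub",
               score_fun = function(fit, x_test) x_test[1, ])
  for (r in cv$per_fold) {
    expect_equal(r$accuracy, 1.0)
    expect_equal(r$auc, 1.0)
  }
  expect_equal(cv$mean$accuracy, 1.0)
  expect_equal(cv$pooled$auc, 1.0)
})

test_that("a constant scorer gives AUC 0.5 in every fold", {
  d <- label_coded_data(40)
  cv <- run_cv(NULL, d$x, d$labels, train_config(seed = 6),
               fit_fun = function(x, y, fold) "stub",
               score_fun = function(fit, x_test) rep(0.5, ncol(x_test)))
  for (r in cv$per_fold) expect_equal(r$auc, 0.5)
})

test_that("fold aggregates lie within the per-fold range", {
  d <- label_coded_data(50)
  cv <- run_cv(NULL, d$x, d$labels, train_config(seed = 8),
               fit_fun = function(x, y, fold) "stub",
               score_fun = function(fit, x_test)
                 pmin(pmax(x_test[1, ] + rnorm(ncol(x_test), sd = 0.4), 0), 1))
  for (m in c("f_score", "accuracy", "sensitivity", "auc")) {
    vals <- vapply(cv$per_fold, `[[`, 0, m)
    expect_gte(cv$mean[[m]], min(vals))
    expect_lte(cv$mean[[m]], max(vals))
  }
})

test_that("training errors are reported with the fold attached", {
  d <- label_coded_data(20)
  expect_error(
    run_cv(NULL, d$x, d$labels, train_config(seed = 1),
           fit_fun = function(x, y, fold) stop("boom"),
           score_fun = function(fit, x_test) rep(0.5, ncol(x_test))),
    "fold 1: boom")
})

test_that("the experiment matrix runs requested cells and lists failures", {
  sizes <- c(16L, 32L)
  datasets <- lapply(setNames(as.character(sizes), as.character(sizes)),
                     function(s) {
    d <- generate_patch_dataset(n_pos = 15, n_neg = 15,
                                size = as.integer(s), seed = 3)
    list(patches = d$patches, labels = d$labels)
  })
  cfg <- function(model, size) train_config(epochs = 1L, batch_size = 16L,
                                            seed = 2L)
  em <- run_experiment_matrix(datasets, models = c("M1", "M3"), sizes = sizes,
                              config_for = cfg)
  # M3 at 16 collapses -> failed; other three cells run
  expect_equal(nrow(em$results), 3L)
  expect_equal(nrow(em$failed), 1L)
  expect_equal(em$failed$model, "M3")
  expect_equal(em$failed$patch_size, 16L)
  expect_identical(colnames(em$results),
                   c("model", "patch_size", "F-score (%)", "Accuracy (%)",
                     "Sensitivity (%)", "AUC (%)"))
  # a single requested model yields one row per available size
  em1 <- run_experiment_matrix(datasets["16"], models = "M1", sizes = 16L,
                               config_for = cfg)
  expect_equal(nrow(em1$results), 1L)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_experiment_matrix(em, csv = csv)
  expect_equal(nrow(utils::read.csv(csv, check.names = FALSE)), 3L)
})
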