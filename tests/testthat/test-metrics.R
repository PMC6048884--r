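test_that("confusion tables match a per-item tally, including the tie rule", {
  ct <- confusion_from_scores(c(1, 0), c(0.9, 0.1))
  expect_equal(unlist(ct[c("tp", "tn", "fp", "fn")]),
               c(tp = 1L, tn = 1L, fp = 0L, fn = 0L))

  # score exactly at threshold predicts the positive class
  ct <- confusion_from_scores(c(1, 0, 1), c(0.5, 0.5, 0.5))
  expect_equal(ct$fp, 1L)
  expect_equal(ct$tp, 2L)
  expect_equal(ct$tn + ct$fn, 0L)

  set.seed(7)
  labels <- rbinom(200, 1, 0.4)
  scores <- round(runif(200), 2)  # ties occur
  ct <- confusion_from_scores(labels, scores)
  expect_equal(unlist(ct), as.integer(oracle_confusion(labels, scores)),
               ignore_attr = TRUE)
  expect_equal(ct_total <- ct$tp + ct$fp + ct$fn + ct$tn, 200L)

  expect_error(confusion_from_scores(numeric(0), numeric(0)), "empty")
})

test_that("per-class precision and recall follow the class-swap definitions", {
  ct <- confusion_table(tp = 80, fp = 10, fn = 20, tn = 90)
  expect_equal(precision_by_class(ct, 1), 8 / 9)
  expect_equal(recall_by_class(ct, 1), 0.8)
  expect_equal(recall_by_class(ct, 0), 0.9)
  expect_equal(precision_by_class(ct, 0), 90 / 110)

  # zero-denominator rule
  empty_pos <- confusion_table(tp = 0, fp = 0, fn = 5, tn = 5)
  expect_identical(precision_by_class(empty_pos, 1), 0)
})

test_that("average F-score equals the worked values and handles degeneracy", {
  expect_equal(average_f_score(confusion_table(80, 10, 20, 90)),
               0.8496, tolerance = 1e-4)
  # perfect classifier: each class term is forced to 1/2
  expect_equal(average_f_score(confusion_table(50, 0, 0, 50)), 1.0)
  # single-class degenerate: class-0 term contributes 0
  expect_equal(average_f_score(confusion_table(100, 0, 0, 0)), 0.5)
})

test_that("two-class average F-score is the macro-averaged F1 (identity)", {
  set.seed(11)
  for (i in 1:500) {
    ct <- random_confusion_table()
    expect_equal(average_f_score(ct),
                 oracle_macro_f1(ct$tp, ct$fp, ct$fn, ct$tn),
                 tolerance = 1e-12)
  }
})

test_that("accuracy and sensitivity are the stated ratios", {
  ct <- confusion_table(80, 10, 20, 90)
  expect_equal(accuracy(ct), 0.85)
  expect_equal(sensitivity(ct), 0.8)
  expect_equal(accuracy(confusion_table(10, 0, 0, 10)), 1.0)
  expect_equal(accuracy(confusion_table(0, 10, 10, 0)), 0.0)
  expect_equal(sensitivity(confusion_table(5, 3, 0, 2)), 1.0)
  expect_equal(sensitivity(confusion_table(0, 3, 5, 2)), 0.0)
})

test_that("ROC endpoints, monotonicity and trapezoidal AUC are correct", {
  r <- roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.7, 0.4))
  expect_equal(r$auc, 1.0)
  expect_equal(r$roc$fpr[1], 0); expect_equal(r$roc$tpr[1], 0)
  expect_equal(tail(r$roc$fpr, 1), 1); expect_equal(tail(r$roc$tpr, 1), 1)
  expect_true(all(diff(r$roc$fpr) >= 0), all(diff(r$roc$tpr) >= 0))

  # 3 of 4 positive-negative pairs correctly ordered
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.3, 0.5, 0.1))$auc, 0.75)
  # all tied: half credit
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.4, 4))$auc, 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.4)), "both classes")
})

test_that("trapezoidal AUC equals Mann-Whitney pair counting with ties", {
  set.seed(13)
  for (i in 1:300) {
    n <- sample(5:60, 1)
    labels <- c(1, 0, rbinom(n, 1, runif(1, 0.2, 0.8)))
    scores <- round(runif(n + 2), sample(1:3, 1))  # coarse grid forces ties
    expect_equal(roc_auc(labels, scores)$auc,
                 oracle_auc_pairs(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  labels <- rbinom(300, 1, 0.45)
  labels[1:2] <- c(0, 1)
  scores <- runif(300)
  expect_equal(roc_auc(labels, scores)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("accuracy is invariant under class relabel plus score reflection", {
  set.seed(19)
  labels <- rbinom(150, 1, 0.5)
  scores <- runif(150)          # continuous, so no exact-threshold ties
  a1 <- accuracy(confusion_from_scores(labels, scores))
  a2 <- accuracy(confusion_from_scores(1 - labels, 1 - scores))
  expect_equal(a1, a2)
})

test_that("metric reports are fractions and the table renders percentages", {
  set.seed(23)
  labels <- c(0, 1, rbinom(80, 1, 0.5))
  scores <- runif(82)
  rep <- metric_report(labels, scores)
  vals <- unlist(rep[c("f_score", "accuracy", "sensitivity", "auc")])
  expect_true(all(vals >= 0 & vals <= 1))
  tab <- format_metric_table(list(run = rep))
  expect_identical(colnames(tab),
                   c("F-score (%)", "Accuracy (%)", "Sensitivity (%)", "AUC (%)"))
  expect_equal(tab[["Accuracy (%)"]], 100 * rep$accuracy)
})
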