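#' Confusion table for the micro-nodule / non-nodule decision
#'
#' Builds the 2x2 confusion table from binary labels and class-1 scores.
#' Class 1 (micro-nodule) is the positive class; a score greater than or
#' equal to `threshold` predicts class 1 (ties therefore go to the positive
#' class, since no decision threshold is prescribed for the classifier).
#'
#' @param labels integer or numeric vector of 0/1 labels
#'   (1 = micro-nodule, 0 = non-nodule).
#' @param scores numeric vector in \[0, 1\], predicted probability of class 1.
#' @param threshold decision threshold, default 0.5.
#' @return An object of class `"confusion_table"`: a list with integer
#'   counts `tp`, `fp`, `fn`, `tn`.
#' @examples
#' ct <- confusion_from_scores(c(1, 0), c(0.9, 0.1))
#' accuracy(ct)
#' @export
confusion_from_scores <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) stop("empty input: no labels/scores to tabulate")
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 1))
    stop("scores must be finite and within [0, 1]")
  pred <- as.integer(scores >= threshold)
  confusion_table(
    tp = sum(pred == 1L & labels == 1L),
    fp = sum(pred == 1L & labels == 0L),
    fn = sum(pred == 0L & labels == 1L),
    tn = sum(pred == 0L & labels == 0L)
  )
}

#' Construct a confusion table from counts
#'
#' @param tp,fp,fn,tn non-negative integer counts. `tp` counts micro-nodules
#'   labelled 1 by the classifier, `tn` non-nodules labelled 0.
#' @return An object of class `"confusion_table"`.
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  structure(lapply(as.list(counts), as.integer), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(`predicted` = c("1", "0"),
                              `actual` = c("micro-nodule (1)", "non-nodule (0)")))
  cat("Confusion table (positive class: micro-nodule)\n")
  print(m)
  invisible(x)
}

ct_total <- function(ct) ct$tp + ct$fp + ct$fn + ct$tn

# denominator-zero rule: an undefined precision/recall contributes 0, keeping
# the two-class F-score total on degenerate folds
safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Per-class precision
#'
#' Precision of the requested class: TP/(TP+FP) for class 1 (micro-nodule)
#' and TN/(TN+FN) for class 0 (non-nodule, obtained by swapping the
#' positive class). A zero denominator yields 0.
#'
#' @param ct a `confusion_table`.
#' @param class_id 1 or 0.
#' @return Fraction in \[0, 1\].
#' @export
precision_by_class <- function(ct, class_id) {
  stopifnot(inherits(ct, "confusion_table"), class_id %in% c(0, 1))
  if (class_id == 1) safe_ratio(ct$tp, ct$tp + ct$fp)
  else safe_ratio(ct$tn, ct$tn + ct$fn)
}

#' Per-class recall
#'
#' Recall of the requested class: TP/(TP+FN) for class 1 and TN/(TN+FP) for
#' class 0. A zero denominator yields 0.
#'
#' @inheritParams precision_by_class
#' @return Fraction in \[0, 1\].
#' @export
recall_by_class <- function(ct, class_id) {
  stopifnot(inherits(ct, "confusion_table"), class_id %in% c(0, 1))
  if (class_id == 1) safe_ratio(ct$tp, ct$tp + ct$fn)
  else safe_ratio(ct$tn, ct$tn + ct$fp)
}

#' Average F-score over the two classes
#'
#' The score is the sum over both classes of
#' \eqn{P_C R_C / (P_C + R_C)}; each class term is half that class's F1, so
#' for two classes the sum equals the macro-averaged F1. A class whose
#' precision and recall are both zero contributes 0.
#'
#' @param ct a `confusion_table` with a positive total.
#' @return Fraction in \[0, 1\].
#' @examples
#' average_f_score(confusion_table(tp = 80, fp = 10, fn = 20, tn = 90))
#' @export
average_f_score <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  if (ct_total(ct) == 0) stop("confusion table is empty")
  term <- function(cls) {
    p <- precision_by_class(ct, cls)
    r <- recall_by_class(ct, cls)
    if (p + r == 0) 0 else p * r / (p + r)
  }
  term(1) + term(0)
}

#' Classification accuracy
#'
#' Correctly classified patches over all patches: (TP+TN)/(TP+TN+FP+FN).
#'
#' @inheritParams average_f_score
#' @return Fraction in \[0, 1\].
#' @export
accuracy <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  n <- ct_total(ct)
  if (n == 0) stop("confusion table is empty")
  (ct$tp + ct$tn) / n
}

#' Sensitivity (true positive rate)
#'
#' Fraction of true micro-nodules labelled 1; identical to class-1 recall.
#'
#' @inheritParams average_f_score
#' @return Fraction in \[0, 1\].
#' @export
sensitivity <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  recall_by_class(ct, 1)
}

#' ROC curve and AUC
#'
#' Sweeps the unique scores as decision thresholds in descending order (tied
#' scores advance jointly), yielding an ROC curve with endpoints (0,0) at
#' threshold +Inf and (1,1) at threshold -Inf. The AUC is the trapezoidal
#' area under this curve, which equals the probability that a random
#' micro-nodule is scored above a random non-nodule, with half credit for
#' tied pairs.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores numeric scores, higher means more micro-nodule-like.
#' @return A list with `roc` (data.frame: `threshold`, `fpr`, `tpr`) of class
#'   `"roc_data"` and `auc` (scalar in \[0, 1\]).
#' @examples
#' roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.7, 0.4))$auc
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores))
    stop("labels and scores must have equal length")
  if (any(!is.finite(scores))) stop("scores must be finite")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC undefined: both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  # advance through tied scores jointly
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y == 1L)[last]
  fp <- cumsum(y == 0L)[last]
  roc <- data.frame(
    threshold = c(Inf, s[last], -Inf),
    fpr = c(0, fp / n_neg, 1),
    tpr = c(0, tp / n_pos, 1)
  )
  class(roc) <- c("roc_data", "data.frame")
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Full metric report for one set of predictions
#'
#' Computes the four evaluation metrics (average F-score, accuracy, sensitivity,
#' AUC) from labels and class-1 scores. All values are fractions in \[0, 1\];
#' use [format_metric_table()] to render them as the percentage columns used
#' in results tables.
#'
#' @inheritParams confusion_from_scores
#' @return A list of class `"metric_report"` with elements `f_score`,
#'   `accuracy`, `sensitivity`, `auc`, `n`.
#' @export
metric_report <- function(labels, scores, threshold = 0.5) {
  ct <- confusion_from_scores(labels, scores, threshold)
  structure(list(
    f_score = average_f_score(ct),
    accuracy = accuracy(ct),
    sensitivity = sensitivity(ct),
    auc = roc_auc(labels, scores)$auc,
    n = length(labels)
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  cat(sprintf("F-score %.2f%%  Accuracy %.2f%%  Sensitivity %.2f%%  AUC %.2f%%  (n = %d)\n",
              100 * x$f_score, 100 * x$accuracy, 100 * x$sensitivity,
              100 * x$auc, x$n))
  invisible(x)
}

#' Render metric reports as a percentage table
#'
#' @param reports a named list of `metric_report` objects (names become row
#'   labels), or a single report.
#' @return data.frame with columns `F-score (%)`, `Accuracy (%)`,
#'   `Sensitivity (%)`, `AUC (%)` — fractions multiplied by 100.
#' @export
format_metric_table <- function(reports) {
  if (inherits(reports, "metric_report")) reports <- list(reports)
  rows <- lapply(reports, function(r)
    data.frame(`F-score (%)` = 100 * r$f_score,
               `Accuracy (%)` = 100 * r$accuracy,
               `Sensitivity (%)` = 100 * r$sensitivity,
               `AUC (%)` = 100 * r$auc,
               check.names = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- names(reports)
  out
}
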