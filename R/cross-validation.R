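#' Stratified k-fold assignment
#'
#' Partitions patch indices into `k` disjoint, exhaustive folds whose sizes
#' differ by at most one, stratified so each fold's label ratio matches the
#' global ratio to within one item per class. Reproducible given `seed`:
#' within each class the indices are shuffled once and dealt cyclically,
#' with the dealing position carried across classes so overall fold sizes
#' stay balanced.
#'
#' @param labels 0/1 vector, one entry per patch.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return An object of class `"fold_assignment"`: list with `k` and
#'   `fold`, an integer vector in `1..k` parallel to `labels`.
#' @examples
#' f <- make_folds(rep(c(0, 1), 50), k = 5, seed = 1)
#' table(f$fold)
#' @export
make_folds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.integer(labels)
  n <- length(labels)
  k <- as.integer(k)
  if (n < k) stop("need at least k = ", k, " items, got ", n)
  set.seed(seed)
  fold <- integer(n)
  offset <- 0L
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- (offset + length(idx)) %% k
  }
  structure(list(k = k, fold = fold, seed = as.integer(seed)),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("%d-fold assignment of %d items (seed %d)\n",
              x$k, length(x$fold), x$seed))
  print(table(fold = x$fold))
  invisible(x)
}

default_fit_fun <- function(arch, config) {
  function(x_train, y_train, fold) {
    cfg <- config
    cfg$seed <- config$seed + fold - 1L   # distinct but derived seeds per fold
    train_cnn(arch, x_train, y_train, cfg)
  }
}

#' Fivefold cross-validation of a patch classifier
#'
#' For each fold, trains on the other `k - 1` folds and scores the held-out
#' fold, so every patch is scored exactly once. Returns per-fold metric
#' reports, their unweighted mean, and — for audit — metrics over the
#' pooled out-of-fold predictions.
#'
#' Folds are split at patch level, not patient level; when multiple readers
#' mark the same lesion, patches from one patient can appear on both sides
#' of a split, which is the protocol evaluated here but optimistic for
#' generalization claims.
#'
#' @param arch an `architecture_spec` (ignored when `fit_fun` is given).
#' @param x patches (`[s, s, n]` array or `s^2 x n` matrix).
#' @param y 0/1 labels.
#' @param config a [train_config()]; also seeds the fold split.
#' @param k number of folds, default 5.
#' @param fit_fun optional `function(x_train, y_train, fold)` returning any
#'   object accepted by `score_fun`; defaults to [train_cnn()] on `arch`.
#' @param score_fun optional `function(fit, x_test)` returning class-1
#'   scores; defaults to [predict.cnn_fit()].
#' @param folds optional precomputed [make_folds()] assignment.
#' @return An object of class `"cv_result"`: list with `experiment`
#'   (model/size), `folds`, `per_fold` (list of `metric_report`), `mean`
#'   and `pooled` reports, and `predictions` (data.frame: index, fold,
#'   label, score).
#' @export
run_cv <- function(arch, x, y, config = train_config(), k = 5L,
                   fit_fun = NULL, score_fun = NULL, folds = NULL) {
  y <- as.integer(y)
  n <- length(y)
  if (n == 0L) stop("empty dataset")
  if (is.null(fit_fun)) {
    stopifnot(inherits(arch, "architecture_spec"))
    fit_fun <- default_fit_fun(arch, config)
  }
  if (is.null(score_fun)) score_fun <- function(fit, x_test) predict(fit, x_test)
  if (is.null(folds)) folds <- make_folds(y, k = k, seed = config$seed)
  k <- folds$k
  x <- if (is.matrix(x)) x else matrix(x, nrow = prod(dim(x)[1:2]), ncol = n)
  scores <- rep(NA_real_, n)
  fold_of <- folds$fold
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold_of == f)
    train_idx <- which(fold_of != f)
    fit <- tryCatch(fit_fun(x[, train_idx, drop = FALSE], y[train_idx], f),
                    error = function(e) stop("fold ", f, ": ", conditionMessage(e),
                                             call. = FALSE))
    s <- score_fun(fit, x[, test_idx, drop = FALSE])
    if (length(s) != length(test_idx))
      stop("fold ", f, ": scorer returned ", length(s), " scores for ",
           length(test_idx), " patches")
    scores[test_idx] <- s
    per_fold[[f]] <- metric_report(y[test_idx], s)
  }
  stopifnot(!anyNA(scores))  # every patch scored exactly once
  mean_report <- structure(list(
    f_score = mean(vapply(per_fold, `[[`, 0, "f_score")),
    accuracy = mean(vapply(per_fold, `[[`, 0, "accuracy")),
    sensitivity = mean(vapply(per_fold, `[[`, 0, "sensitivity")),
    auc = mean(vapply(per_fold, `[[`, 0, "auc")),
    n = n), class = "metric_report")
  structure(list(
    experiment = list(model = if (inherits(arch, "architecture_spec")) arch$name else NA_character_,
                      patch_size = if (inherits(arch, "architecture_spec")) arch$input_size else NA_integer_),
    folds = folds,
    per_fold = per_fold,
    mean = mean_report,
    pooled = metric_report(y, scores),
    predictions = data.frame(index = seq_len(n), fold = fold_of,
                             label = y, score = scores)
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Fivefold CV: model %s, patch size %s (n = %d)\n",
              x$experiment$model, x$experiment$patch_size, nrow(x$predictions)))
  cat("mean over folds:   "); print(x$mean)
  cat("pooled (audit):    "); print(x$pooled)
  invisible(x)
}

#' Cross-validated experiment matrix over models and patch sizes
#'
#' Runs [run_cv()] for every requested model (`M1`, `M2`, `M3`) and patch
#' size (16, 32, 64) for which a dataset is supplied — the full 3 x 3
#' depth-by-receptive-field comparison. Cells whose architecture rejects the patch size (M3 at
#' 16, whose feature map collapses) or whose dataset is missing are listed
#' in `failed` and the remaining cells still run.
#'
#' @param datasets named list keyed by patch size (`"16"`, `"32"`, `"64"`),
#'   each a list with `patches` and `labels`.
#' @param models character vector of model names.
#' @param sizes integer vector of patch sizes.
#' @param config_for `function(model, size)` returning the [train_config()]
#'   for that cell. The default applies the reference protocol: lr 0.0001,
#'   momentum 0.9, 50 epochs — 120 for M2, which converges more slowly.
#' @param seed base seed used by the default `config_for`.
#' @return A list of class `"experiment_matrix"`: `results` (data.frame
#'   with model, patch_size and the four percentage metrics averaged over
#'   folds), `cv` (named list of `cv_result`), `failed` (data.frame of
#'   skipped cells with reasons).
#' @export
run_experiment_matrix <- function(datasets, models = c("M1", "M2", "M3"),
                                  sizes = c(16L, 32L, 64L),
                                  config_for = NULL, seed = 1L) {
  if (is.null(config_for))
    config_for <- function(model, size)
      train_config(epochs = if (model == "M2") 120L else 50L, seed = seed)
  results <- list(); cvs <- list(); failed <- list()
  for (model in models) for (size in sizes) {
    key <- paste0(model, "_", size)
    ds <- datasets[[as.character(size)]]
    cell <- tryCatch({
      if (is.null(ds)) stop("no dataset for patch size ", size)
      arch <- build_architecture(model, size)
      run_cv(arch, ds$patches, ds$labels, config_for(model, size))
    }, error = function(e) e)
    if (inherits(cell, "error")) {
      failed[[key]] <- data.frame(model = model, patch_size = size,
                                  reason = conditionMessage(cell))
      next
    }
    cvs[[key]] <- cell
    results[[key]] <- data.frame(
      model = model, patch_size = size,
      `F-score (%)` = 100 * cell$mean$f_score,
      `Accuracy (%)` = 100 * cell$mean$accuracy,
      `Sensitivity (%)` = 100 * cell$mean$sensitivity,
      `AUC (%)` = 100 * cell$mean$auc,
      check.names = FALSE)
  }
  structure(list(results = if (length(results))
                   do.call(rbind, c(results, list(make.row.names = FALSE)))
                 else NULL,
                 cv = cvs,
                 failed = if (length(failed))
                   do.call(rbind, c(failed, list(make.row.names = FALSE)))
                 else NULL),
            class = "experiment_matrix")
}

#' @export
print.experiment_matrix <- function(x, digits = 2, ...) {
  cat("Cross-validated model x patch-size comparison\n")
  res <- x$results
  num <- vapply(res, is.numeric, TRUE) & names(res) != "patch_size"
  res[num] <- lapply(res[num], round, digits)
  print(res, row.names = FALSE)
  if (!is.null(x$failed)) {
    cat("skipped cells:\n")
    print(x$failed, row.names = FALSE)
  }
  invisible(x)
}

#' Write an experiment matrix to CSV/JSON
#'
#' @param x an `experiment_matrix`.
#' @param csv,json optional output paths.
#' @return `x`, invisibly.
#' @export
write_experiment_matrix <- function(x, csv = NULL, json = NULL) {
  stopifnot(inherits(x, "experiment_matrix"))
  if (!is.null(csv)) utils::write.csv(x$results, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(x$results, json, dataframe = "rows", digits = NA)
  invisible(x)
}
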