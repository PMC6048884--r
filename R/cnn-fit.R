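#' Training configuration
#'
#' Optimizer and schedule settings for [train_cnn()]. The defaults are the
#' reference protocol: SGD with learning rate 0.0001, momentum 0.9 and 50
#' epochs (120 is the optimized epoch count for M2), minibatches of 128
#' with a seeded reshuffle every epoch, and 2-class softmax cross-entropy
#' loss.
#'
#' @param learning_rate positive step size.
#' @param momentum SGD momentum in \[0, 1).
#' @param epochs non-negative integer; 0 returns the untrained model.
#' @param batch_size minibatch size.
#' @param seed integer seed fixing weight initialization, epoch shuffling
#'   and dropout.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 1e-4, momentum = 0.9, epochs = 50L,
                         batch_size = 128L, seed = 1L) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1,
            epochs >= 0, batch_size >= 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Accept patches as [s, s, n] arrays or (s*s) x n matrices; return s^2 x n.
patches_as_matrix <- function(x, input_size) {
  if (is.array(x) && length(dim(x)) == 3L) {
    d <- dim(x)
    if (d[1] != d[2]) stop("patch array must be square in its first two dims")
    x <- matrix(x, nrow = d[1] * d[2], ncol = d[3])
  }
  if (!is.matrix(x)) stop("patches must be a [s, s, n] array or a (s^2 x n) matrix")
  if (nrow(x) != input_size^2)
    stop("patch size ", sqrt(nrow(x)), " does not match architecture input ",
         input_size)
  storage.mode(x) <- "double"
  x
}

engine_layers <- function(arch) lapply(arch$layers, unclass)

#' Initialize network weights
#'
#' Variance-scaling uniform initialization (He scaling, uniform on
#' `[-sqrt(6/fan_in), sqrt(6/fan_in)]`, the standard choice for
#' rectifier networks) for every convolutional and dense layer; biases
#' start at zero. Draws come from R's RNG, so wrap in `set.seed()` (or use
#' [train_cnn()], which seeds for you) for reproducible runs.
#'
#' @param arch an `architecture_spec`.
#' @return A list parallel to `arch$layers`; parameterized layers hold
#'   `W` and `b` matrices, others `NULL`.
#' @export
init_cnn_weights <- function(arch) {
  shapes <- propagate_shapes(arch)
  n_in_prev <- arch$input_size^2   # flattened input size
  c_prev <- 1L
  weights <- vector("list", length(arch$layers))
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    if (ly$kind == "conv") {
      fan_in <- prod(ly$kernel) * c_prev
      lim <- sqrt(6 / fan_in)
      weights[[i]] <- list(
        W = matrix(stats::runif(fan_in * ly$filters, -lim, lim),
                   nrow = fan_in, ncol = ly$filters),
        b = matrix(0, ly$filters, 1))
    } else if (ly$kind == "dense") {
      lim <- sqrt(6 / n_in_prev)
      weights[[i]] <- list(
        W = matrix(stats::runif(n_in_prev * ly$units, -lim, lim),
                   nrow = n_in_prev, ncol = ly$units),
        b = matrix(0, ly$units, 1))
    }
    n_in_prev <- shapes$n_out[i]
    c_prev <- shapes$out_c[i]
  }
  weights
}

#' Fit a patch-classification CNN
#'
#' Trains an architecture from [build_m1()], [build_m2()] or [build_m3()]
#' on labelled intensity patches by minibatch SGD with momentum on the
#' 2-class softmax cross-entropy. Per-iteration training loss and accuracy
#' are recorded (the training history).
#'
#' Inputs are zero-centred by default: the training-set mean intensity is
#' subtracted before training (and again, with the same stored value, at
#' prediction time). This mirrors the default input normalization of
#' mainstream training frameworks and markedly speeds optimization at the
#' default small learning rate; set `center = FALSE` to feed raw
#' intensities.
#'
#' @param arch an `architecture_spec`; its `input_size` must match the
#'   patches.
#' @param x patches: `[s, s, n]` array or `(s^2 x n)` matrix of intensities
#'   in \[0, 1\].
#' @param y length-n vector of 0/1 labels (1 = micro-nodule).
#' @param config a [train_config()].
#' @param weights optional initial weights (as from [init_cnn_weights()]);
#'   defaults to a fresh seeded initialization.
#' @param center subtract the training-set mean intensity (default `TRUE`).
#' @return An object of class `"cnn_fit"`: list with `arch`, `weights`,
#'   `history` (data.frame: iteration, epoch, loss, accuracy), `config`,
#'   `center` (the stored intensity offset).
#' @seealso [predict.cnn_fit()], [run_cv()]
#' @examples
#' set.seed(1)
#' d <- generate_patch_dataset(n_pos = 60, n_neg = 60, size = 16,
#'                             separation = 4, seed = 7)
#' fit <- train_cnn(build_m1(16), d$patches, d$labels,
#'                  train_config(epochs = 2, seed = 1))
#' head(predict(fit, d$patches, type = "score"))
#' @export
train_cnn <- function(arch, x, y, config = train_config(), weights = NULL,
                      center = TRUE) {
  stopifnot(inherits(arch, "architecture_spec"), inherits(config, "train_config"))
  propagate_shapes(arch)  # fail early on invalid geometry
  x <- patches_as_matrix(x, arch$input_size)
  y <- as.integer(y)
  if (length(y) != ncol(x)) stop("length(y) must equal the number of patches")
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  offset <- if (center) mean(x) else 0
  if (center) x <- x - offset
  set.seed(config$seed)
  if (is.null(weights)) weights <- init_cnn_weights(arch)
  res <- .cpp_cnn_train(engine_layers(arch), weights, x,
                        c(arch$input_size, arch$input_size, 1L), y,
                        config$learning_rate, config$momentum,
                        config$epochs, config$batch_size)
  structure(list(arch = arch, weights = res$weights, history = res$history,
                 config = config, center = offset, n_train = ncol(x)),
            class = "cnn_fit")
}

#' Predict from a fitted patch CNN
#'
#' @param object a `cnn_fit`.
#' @param newdata patches as in [train_cnn()].
#' @param type `"score"` (default) returns the class-1 probability vector,
#'   `"prob"` the n x 2 probability matrix, `"class"` hard 0/1 labels at
#'   threshold 0.5 (ties to class 1).
#' @param ... unused.
#' @return See `type`.
#' @export
predict.cnn_fit <- function(object, newdata,
                            type = c("score", "prob", "class"), ...) {
  type <- match.arg(type)
  x <- patches_as_matrix(newdata, object$arch$input_size) - object$center
  probs <- .cpp_cnn_predict(engine_layers(object$arch), object$weights, x,
                            c(object$arch$input_size, object$arch$input_size, 1L))
  colnames(probs) <- c("0", "1")
  switch(type,
         prob = probs,
         score = probs[, 2L],
         class = as.integer(probs[, 2L] >= 0.5))
}

#' @export
print.cnn_fit <- function(x, ...) {
  cat(sprintf("Patch CNN fit: %s, input %dx%d, %d training patches\n",
              x$arch$name, x$arch$input_size, x$arch$input_size, x$n_train))
  cat(sprintf("  SGD lr %g, momentum %g, %d epochs, batch %d, seed %d\n",
              x$config$learning_rate, x$config$momentum, x$config$epochs,
              x$config$batch_size, x$config$seed))
  if (nrow(x$history)) {
    last <- utils::tail(x$history, 1)
    cat(sprintf("  final batch loss %.4f, batch accuracy %.3f (%d iterations)\n",
                last$loss, last$accuracy, nrow(x$history)))
  } else cat("  untrained (0 epochs)\n")
  invisible(x)
}

#' @export
summary.cnn_fit <- function(object, ...) {
  print(object)
  print(object$arch)
  invisible(object)
}

#' @export
coef.cnn_fit <- function(object, ...) object$weights

#' Plot training history
#'
#' Per-iteration training loss and accuracy of a fitted patch CNN.
#'
#' @param x a `cnn_fit`.
#' @param ... passed to [plot()].
#' @export
plot.cnn_fit <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) {
    warning("no training history to plot")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(h$iteration, h$loss, type = "l", xlab = "iteration",
       ylab = "training loss", main = x$arch$name, ...)
  plot(h$iteration, h$accuracy, type = "l", xlab = "iteration",
       ylab = "training accuracy", ylim = c(0, 1), main = x$arch$name, ...)
  invisible(x)
}
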