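engine_layers <- function(arch) lapply(arch$layers, unclass)

test_that("backpropagated gradients match central finite differences", {
  arch <- tiny_arch()
  set.seed(42)
  w <- init_cnn_weights(arch)
  x <- matrix(runif(64 * 6), 64, 6)
  y <- c(0L, 1L, 1L, 0L, 1L, 0L)
  L <- engine_layers(arch)
  lg <- micronodule:::.cpp_cnn_loss_grad(L, w, x, c(8L, 8L, 1L), y)
  expect_true(is.finite(lg$loss))
  eps <- 1e-3
  rel <- c()
  for (li in seq_along(w)) {
    if (is.null(w[[li]])) next
    for (nm in c("W", "b")) {
      idx <- sample(length(w[[li]][[nm]]), min(8, length(w[[li]][[nm]])))
      for (j in idx) {
        an <- lg$grads[[li]][[nm]][j]
        # below the single-precision noise floor of a central difference
        # the comparison is uninformative
        if (abs(an) < 5e-3) next
        wp <- w; wp[[li]][[nm]][j] <- wp[[li]][[nm]][j] + eps
        wm <- w; wm[[li]][[nm]][j] <- wm[[li]][[nm]][j] - eps
        fd <- (micronodule:::.cpp_cnn_loss_grad(L, wp, x, c(8L, 8L, 1L), y)$loss -
               micronodule:::.cpp_cnn_loss_grad(L, wm, x, c(8L, 8L, 1L), y)$loss) /
              (2 * eps)
        rel <- c(rel, abs(fd - an) / max(abs(fd), abs(an)))
      }
    }
  }
  expect_gt(length(rel), 20)
  # a perturbation can flip a maxpool argmax (a true kink where the finite
  # difference, not the analytic gradient, is wrong); require bulk agreement
  expect_lt(median(rel), 2e-3)
  expect_gt(mean(rel < 2e-2), 0.9)
})

test_that("a dense-softmax-only network recovers the logistic regression fit", {
  # 2 features, linearly separable-ish; engine SGD vs glm() as oracle
  set.seed(5)
  n <- 400
  x2 <- matrix(rnorm(2 * n), 2, n)
  logit <- 1.5 * x2[1, ] - 2 * x2[2, ]
  y <- rbinom(n, 1, plogis(logit))
  # embed the 2 features in a 16-pixel "patch" (rest zero)
  x <- rbind(x2, matrix(0, 14, n))
  arch <- structure(list(name = "lr", input_size = 4L, layers = list(
    layer_dense(2L), layer_softmax())), class = "architecture_spec")
  fit <- train_cnn(arch, x, y, train_config(learning_rate = 0.5, momentum = 0.9,
                                            epochs = 200L, batch_size = 400L,
                                            seed = 2L))
  glm_fit <- stats::glm(y ~ t(x2), family = stats::binomial())
  p_cnn <- predict(fit, x)
  p_glm <- as.numeric(stats::fitted(glm_fit))
  # same decision function up to optimization tolerance
  expect_gt(cor(qlogis(pmin(pmax(p_cnn, 1e-6), 1 - 1e-6)),
                qlogis(pmin(pmax(p_glm, 1e-6), 1 - 1e-6))), 0.999)
  expect_equal(roc_auc(y, p_cnn)$auc, roc_auc(y, p_glm)$auc, tolerance = 0.01)
})

test_that("training is reproducible from the seed and respects zero epochs", {
  d <- generate_patch_dataset(n_pos = 30, n_neg = 30, size = 16, seed = 3)
  arch <- build_m1(16)
  cfg <- train_config(epochs = 2L, batch_size = 16L, seed = 9L)
  f1 <- train_cnn(arch, d$patches, d$labels, cfg)
  f2 <- train_cnn(arch, d$patches, d$labels, cfg)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)

  f0 <- train_cnn(arch, d$patches, d$labels, train_config(epochs = 0L, seed = 9L))
  expect_equal(nrow(f0$history), 0L)
  # untrained but usable: probabilities still well-formed
  p <- predict(f0, d$patches, type = "prob")
  expect_equal(rowSums(p), rep(1, 60), tolerance = 1e-6)
})

test_that("predicted class probabilities sum to one and classes threshold at 0.5", {
  d <- generate_patch_dataset(n_pos = 20, n_neg = 20, size = 16, seed = 4)
  fit <- train_cnn(build_m1(16), d$patches, d$labels,
                   train_config(epochs = 1L, batch_size = 8L, seed = 1L))
  p <- predict(fit, d$patches, type = "prob")
  expect_equal(rowSums(p), rep(1, 40), tolerance = 1e-6)
  s <- predict(fit, d$patches, type = "score")
  cls <- predict(fit, d$patches, type = "class")
  expect_identical(cls, as.integer(s >= 0.5))
})

test_that("mismatched patch size and architecture input are rejected", {
  d <- generate_patch_dataset(n_pos = 5, n_neg = 5, size = 16, seed = 6)
  expect_error(train_cnn(build_m2(32), d$patches, d$labels,
                         train_config(epochs = 1L)),
               "does not match")
  fit <- train_cnn(build_m1(16), d$patches, d$labels,
                   train_config(epochs = 0L))
  expect_error(predict(fit, array(0, c(32, 32, 2))), "does not match")
})

test_that("training history tracks every iteration with finite values", {
  d <- generate_patch_dataset(n_pos = 40, n_neg = 40, size = 16, seed = 8)
  fit <- train_cnn(build_m1(16), d$patches, d$labels,
                   train_config(epochs = 3L, batch_size = 32L, seed = 1L))
  # 80 patches / batch 32 -> 3 iterations per epoch
  expect_equal(nrow(fit$history), 9L)
  expect_equal(fit$history$epoch, rep(1:3, each = 3L))
  expect_true(all(is.finite(fit$history$loss)))
  expect_true(all(fit$history$accuracy >= 0 & fit$history$accuracy <= 1))
})
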