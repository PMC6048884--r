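# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force rather than calling the package's own code.

# macro-averaged F1 from per-class precision/recall, guarded like the
# package's zero rule
oracle_macro_f1 <- function(tp, fp, fn, tn) {
  f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
  p1 <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r1 <- if (tp + fn == 0) 0 else tp / (tp + fn)
  p0 <- if (tn + fn == 0) 0 else tn / (tn + fn)
  r0 <- if (tn + fp == 0) 0 else tn / (tn + fp)
  (f1(p1, r1) + f1(p0, r0)) / 2
}

# Mann-Whitney pair counting with half credit for ties
oracle_auc_pairs <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# brute-force per-item confusion tally
oracle_confusion <- function(labels, scores, threshold = 0.5) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(labels)) {
    pred <- if (scores[i] >= threshold) 1L else 0L
    if (pred == 1L && labels[i] == 1L) tp <- tp + 1L
    else if (pred == 1L && labels[i] == 0L) fp <- fp + 1L
    else if (pred == 0L && labels[i] == 1L) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Brute-force shape/parameter audit, written against its own hardcoded
# description of the three architectures (kept independent of build_m*).
# Returns list(shapes = final feature dims before flatten, params = total),
# or the string "collapses" when a spatial dimension hits zero.
oracle_architecture <- function(model, input_size) {
  plans <- list(
    M1 = list(c("conv", 3, 32), c("pool", 2), c("dense", 256), c("dense", 2)),
    M2 = list(c("conv", 7, 64), c("pool", 2), c("conv", 2, 128),
              c("dense", 256), c("dense", 2)),
    M3 = list(c("conv", 3, 32), c("pool", 2), c("conv", 3, 64), c("pool", 2),
              c("conv", 3, 128), c("pool", 2), c("conv", 2, 256),
              c("dense", 256), c("dense", 2))
  )
  n <- input_size; ch <- 1; params <- 0; per_layer <- numeric(0)
  for (step in plans[[model]]) {
    kind <- step[1]; a <- as.numeric(step[2]); b <- as.numeric(step[3])
    if (kind == "conv") {
      n2 <- (n - a) + 1
      if (n2 < 1) return("collapses")
      p <- a * a * ch * b + b
      params <- params + p; per_layer <- c(per_layer, p)
      n <- n2; ch <- b
    } else if (kind == "pool") {
      n2 <- floor((n - a) / a) + 1
      if (n2 < 1) return("collapses")
      n <- n2
    } else {
      n_in <- n * n * ch
      p <- n_in * a + a
      params <- params + p; per_layer <- c(per_layer, p)
      n <- 1; ch <- a
    }
  }
  list(params = params, conv_dense_params = per_layer)
}

# tiny architecture used by engine tests (valid for 8x8 input)
tiny_arch <- function() {
  structure(list(name = "tiny", input_size = 8L, layers = list(
    layer_conv(3L, c(3L, 3L)),
    layer_relu(),
    layer_maxpool(),
    layer_conv(4L, c(2L, 2L)),
    layer_dense(5L),
    layer_dense(2L),
    layer_softmax()
  )), class = "architecture_spec")
}

random_confusion_table <- function() {
  n <- sample(0:200, 4, replace = TRUE)
  if (sum(n) == 0) n[1] <- 1
  confusion_table(tp = n[1], fp = n[2], fn = n[3], tn = n[4])
}
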