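#' @name layers
#' @title Layer specification helpers
#'
#' @description Framework-independent layer descriptions used to assemble the
#' three model architectures. Convolutions and poolings are valid (no
#' padding); conv stride is 1 and pooling defaults to 2x2 with stride 2.
#'
#' @param filters number of convolution filters.
#' @param kernel `(h, w)` kernel size.
#' @param stride `(h, w)` stride.
#' @param units dense layer width.
#' @param rate dropout rate in (0, 1).
#' @return A list describing the layer, class `"layer_spec"`.
NULL

layer <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "layer_spec")
}

#' @rdname layers
#' @export
layer_conv <- function(filters, kernel, stride = c(1L, 1L)) {
  stopifnot(filters >= 1, length(kernel) == 2, all(kernel >= 1))
  layer("conv", filters = as.integer(filters), kernel = as.integer(kernel),
        stride = as.integer(stride))
}

#' @rdname layers
#' @export
layer_relu <- function() layer("relu")

#' @rdname layers
#' @export
layer_maxpool <- function(kernel = c(2L, 2L), stride = c(2L, 2L)) {
  stopifnot(length(kernel) == 2, all(kernel >= 1))
  layer("maxpool", kernel = as.integer(kernel), stride = as.integer(stride))
}

#' @rdname layers
#' @export
layer_dense <- function(units) {
  stopifnot(units >= 1)
  layer("dense", units = as.integer(units))
}

#' @rdname layers
#' @export
layer_dropout <- function(rate = 0.5) {
  stopifnot(rate > 0, rate < 1)
  layer("dropout", rate = rate)
}

#' @rdname layers
#' @export
layer_softmax <- function() layer("softmax")

new_architecture <- function(name, input_size, layers) {
  structure(list(name = name, input_size = as.integer(input_size),
                 layers = layers),
            class = "architecture_spec")
}

check_input_size <- function(input_size) {
  if (!input_size %in% c(16L, 32L, 64L))
    stop("unsupported input_size ", input_size, ": must be 16, 32 or 64")
  as.integer(input_size)
}

#' The three compared CNN architectures
#'
#' @description
#' `build_m1()`, `build_m2()` and `build_m3()` return the three
#' convolutional network architectures compared in this package, of depth 1,
#' 2 and 4 convolutional layers respectively, for square grayscale CT
#' patches of 16, 32 or 64 pixels:
#'
#' * **M1** — conv (32 filters, 3x3) -> maxpool -> dense(256) ->
#'   dropout(0.5) -> dense(2) -> softmax.
#' * **M2** — conv (64 filters, 7x7) -> ReLU -> maxpool -> conv (128
#'   filters, 2x2) -> dropout(0.5) -> dense(256) -> dense(2) -> softmax.
#' * **M3** — three conv+maxpool stages (32/64/128 filters, 3x3) -> conv
#'   (256 filters, 2x2) -> dropout(0.5) -> dense(256) -> dense(2) ->
#'   softmax.
#'
#' M2's kernel complement (64 filters of 7x7, then 128 of 2x2) is fixed by
#' the reference design; filter counts for M1/M3, the dense width of 256, the
#' dropout rate of 0.5 and the 2x2/2 poolings are package defaults,
#' overridable through the layer helpers. All convolutions are valid
#' (unpadded); M3 therefore rejects 16-pixel input, whose spatial extent
#' collapses under its three poolings.
#'
#' @param input_size patch side length: 16, 32 or 64.
#' @param conv_kernel M1 only: kernel of the single convolution (default
#'   3x3, the size found best for 32x32 patches).
#' @param validate if `TRUE` (default) run [propagate_shapes()] and fail on
#'   a collapsing spatial dimension.
#' @return An object of class `"architecture_spec"`.
#' @examples
#' m2 <- build_m2(32)
#' propagate_shapes(m2)
#' count_params(m2)
#' @export
build_m1 <- function(input_size, conv_kernel = c(3L, 3L), validate = TRUE) {
  input_size <- check_input_size(input_size)
  arch <- new_architecture("M1", input_size, list(
    layer_conv(32L, conv_kernel),
    layer_maxpool(),
    layer_dense(256L),
    layer_dropout(0.5),
    layer_dense(2L),
    layer_softmax()
  ))
  if (validate) propagate_shapes(arch)
  arch
}

#' @rdname build_m1
#' @export
build_m2 <- function(input_size, validate = TRUE) {
  input_size <- check_input_size(input_size)
  arch <- new_architecture("M2", input_size, list(
    layer_conv(64L, c(7L, 7L)),
    layer_relu(),
    layer_maxpool(),
    layer_conv(128L, c(2L, 2L)),
    layer_dropout(0.5),
    layer_dense(256L),
    layer_dense(2L),
    layer_softmax()
  ))
  if (validate) propagate_shapes(arch)
  arch
}

#' @rdname build_m1
#' @export
build_m3 <- function(input_size, validate = TRUE) {
  input_size <- check_input_size(input_size)
  arch <- new_architecture("M3", input_size, list(
    layer_conv(32L, c(3L, 3L)),
    layer_maxpool(),
    layer_conv(64L, c(3L, 3L)),
    layer_maxpool(),
    layer_conv(128L, c(3L, 3L)),
    layer_maxpool(),
    layer_conv(256L, c(2L, 2L)),
    layer_dropout(0.5),
    layer_dense(256L),
    layer_dense(2L),
    layer_softmax()
  ))
  if (validate) propagate_shapes(arch)
  arch
}

#' Build an architecture by name
#'
#' @param name `"M1"`, `"M2"` or `"M3"`.
#' @inheritParams build_m1
#' @export
build_architecture <- function(name, input_size, validate = TRUE) {
  switch(match.arg(name, c("M1", "M2", "M3")),
         M1 = build_m1(input_size, validate = validate),
         M2 = build_m2(input_size, validate = validate),
         M3 = build_m3(input_size, validate = validate))
}

conv_out <- function(n, k, s) floor((n - k) / s) + 1

#' Propagate feature-map shapes through an architecture
#'
#' Applies valid-padding convolution arithmetic,
#' \eqn{n' = \lfloor (n-k)/s \rfloor + 1}, layer by layer. The first dense
#' layer flattens its input. Fails if any spatial dimension becomes
#' non-positive, naming the offending layer.
#'
#' @param arch an `architecture_spec`.
#' @return data.frame with one row per layer: `index`, `kind`, `out_h`,
#'   `out_w`, `out_c` (dense layers report `1 x 1 x units`), `n_out`
#'   (flattened size) and `params` (trainable parameters).
#' @export
propagate_shapes <- function(arch) {
  stopifnot(inherits(arch, "architecture_spec"))
  h <- w <- arch$input_size
  ch <- 1L           # grayscale CT input
  flat <- FALSE
  rows <- vector("list", length(arch$layers))
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    params <- 0
    switch(ly$kind,
      conv = {
        if (flat) stop("layer ", i, " (conv): input already flattened")
        h2 <- conv_out(h, ly$kernel[1], ly$stride[1])
        w2 <- conv_out(w, ly$kernel[2], ly$stride[2])
        if (h2 < 1 || w2 < 1)
          stop("layer ", i, " (conv ", ly$kernel[1], "x", ly$kernel[2],
               "): spatial dimension collapses (", h, "x", w, " input)")
        params <- prod(ly$kernel) * ch * ly$filters + ly$filters
        h <- h2; w <- w2; ch <- ly$filters
      },
      maxpool = {
        if (flat) stop("layer ", i, " (maxpool): input already flattened")
        h2 <- conv_out(h, ly$kernel[1], ly$stride[1])
        w2 <- conv_out(w, ly$kernel[2], ly$stride[2])
        if (h2 < 1 || w2 < 1)
          stop("layer ", i, " (maxpool): spatial dimension collapses (",
               h, "x", w, " input)")
        h <- h2; w <- w2
      },
      dense = {
        n_in <- h * w * ch
        params <- n_in * ly$units + ly$units
        h <- w <- 1L; ch <- ly$units; flat <- TRUE
      },
      relu = , dropout = , softmax = NULL,
      stop("unknown layer kind: ", ly$kind)
    )
    rows[[i]] <- data.frame(index = i, kind = ly$kind, out_h = h, out_w = w,
                            out_c = ch, n_out = h * w * ch, params = params)
  }
  do.call(rbind, rows)
}

#' Count trainable parameters
#'
#' @param arch an `architecture_spec`.
#' @return Total number of trainable parameters (weights + biases) over all
#'   convolutional and dense layers.
#' @export
count_params <- function(arch) sum(propagate_shapes(arch)$params)

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf("Architecture %s (input %dx%dx1)\n",
              x$name, x$input_size, x$input_size))
  sh <- tryCatch(propagate_shapes(x), error = function(e) NULL)
  for (i in seq_along(x$layers)) {
    ly <- x$layers[[i]]
    desc <- switch(ly$kind,
      conv = sprintf("conv %d @ %dx%d", ly$filters, ly$kernel[1], ly$kernel[2]),
      maxpool = sprintf("maxpool %dx%d/%d", ly$kernel[1], ly$kernel[2], ly$stride[1]),
      dense = sprintf("dense %d", ly$units),
      dropout = sprintf("dropout %.2f", ly$rate),
      ly$kind)
    shape <- if (!is.null(sh)) sprintf("-> %dx%dx%d", sh$out_h[i], sh$out_w[i], sh$out_c[i]) else ""
    cat(sprintf("  %2d. %-18s %s\n", i, desc, shape))
  }
  if (!is.null(sh)) cat("  trainable parameters:", sum(sh$params), "\n")
  invisible(x)
}

#' Serialize / deserialize an architecture to JSON
#'
#' @param arch an `architecture_spec`.
#' @param path file path; for `arch_to_json` omit to return the JSON string.
#' @return `arch_to_json`: JSON string (invisibly, if written to `path`);
#'   `arch_from_json`: an `architecture_spec`.
#' @export
arch_to_json <- function(arch, path = NULL) {
  stopifnot(inherits(arch, "architecture_spec"))
  doc <- list(name = arch$name, input_size = arch$input_size,
              layers = lapply(arch$layers, unclass))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' @rdname arch_to_json
#' @param json JSON string (alternative to `path`).
#' @export
arch_from_json <- function(path = NULL, json = NULL) {
  doc <- jsonlite::fromJSON(if (is.null(json)) path else json,
                            simplifyDataFrame = FALSE, simplifyVector = TRUE)
  layers <- lapply(doc$layers, function(ly) {
    ly$kind <- as.character(ly$kind)
    for (f in c("filters", "units")) if (!is.null(ly[[f]])) ly[[f]] <- as.integer(ly[[f]])
    for (f in c("kernel", "stride")) if (!is.null(ly[[f]])) ly[[f]] <- as.integer(ly[[f]])
    structure(ly, class = "layer_spec")
  })
  new_architecture(doc$name, doc$input_size, layers)
}
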