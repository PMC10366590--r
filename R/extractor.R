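#' Initialise the frozen random-weight 3D residual extractor
#'
#' Builds the never-trained convolutional backbone: a 7x7x7 stem convolution
#' with 3x3x3 average pooling, a first residual module of 3 bottleneck blocks
#' (output channels `channels["module1"]`), and a second residual module of 4
#' bottleneck blocks (output channels `channels["module2"]`). All weights are
#' drawn once from the seeded RNG and are never updated; identical
#' `seed` + `init_scheme` give bitwise-identical parameters.
#'
#' Each bottleneck block is `1x1x1 -> 3x3x3 -> 1x1x1` with ReLU activations,
#' an internal width of a quarter of the block's output channels (overridable
#' via `bottleneck_width`), and a projection shortcut where channel count or
#' spatial shape changes. No normalisation layers are used: the network is
#' never trained and variance is controlled by the initialisation instead.
#'
#' The default `"table1"` stride scheme is stem conv `(1,2,2)`, stem pool
#' `(2,2,2)`, module 1 stride 1, module 2 first-block stride `(2,2,2)`, which
#' carries a 224x224x128 input through 224x112x64 -> 112x56x32 -> 112x56x32
#' -> 56x28x16. A `"uniform"` alternative strides the stem conv by 2 on all
#' axes.
#'
#' @param seed Integer RNG seed.
#' @param init_scheme `"he_normal"` (sd = sqrt(2/fan_in), default),
#'   `"he_uniform"`, or `"uniform"` (U\[-1, 1\]).
#' @param channels Named integer vector with elements `stem`, `module1`,
#'   `module2`; defaults `c(stem = 64, module1 = 256, module2 = 512)`. Smaller
#'   values give a cheap extractor for testing; the global-average-pooled
#'   feature lengths equal `module1` and `module2`.
#' @param bottleneck_width Optional named vector overriding the internal
#'   bottleneck widths for the two modules (defaults to a quarter of each
#'   module's output channels).
#' @param stride_scheme `"table1"` (default) or `"uniform"`.
#' @return An object of class `extractor_params`.
#' @export
init_extractor <- function(seed = 42L,
                           init_scheme = c("he_normal", "he_uniform", "uniform"),
                           channels = c(stem = 64L, module1 = 256L, module2 = 512L),
                           bottleneck_width = NULL,
                           stride_scheme = c("table1", "uniform")) {
  init_scheme <- tryCatch(match.arg(init_scheme),
                          error = function(e) stop("unknown init scheme '",
                                                   init_scheme[1], "'", call. = FALSE))
  stride_scheme <- match.arg(stride_scheme)
  channels <- as.integer(channels)
  stopifnot(length(channels) == 3L, all(channels >= 1L))
  names(channels) <- c("stem", "module1", "module2")
  width <- as.integer(bottleneck_width %||%
                        pmax(1L, channels[c("module1", "module2")] %/% 4L))
  stopifnot(length(width) == 2L, all(width >= 1L))

  draw <- function(kdim) {
    fan_in <- prod(kdim[1:4])
    n <- prod(kdim)
    w <- switch(init_scheme,
      he_normal  = rnorm(n, sd = sqrt(2 / fan_in)),
      he_uniform = runif(n, -sqrt(6 / fan_in), sqrt(6 / fan_in)),
      uniform    = runif(n, -1, 1))
    array(w, kdim)
  }
  make_block <- function(c_in, c_out, w, stride) {
    list(w1 = draw(c(1L, 1L, 1L, c_in, w)),  b1 = numeric(w),
         w2 = draw(c(3L, 3L, 3L, w, w)),     b2 = numeric(w),
         w3 = draw(c(1L, 1L, 1L, w, c_out)), b3 = numeric(c_out),
         proj = if (c_in != c_out || any(stride != 1L))
           draw(c(1L, 1L, 1L, c_in, c_out)),
         bproj = numeric(c_out),
         stride = as.integer(stride))
  }
  stem_stride <- if (stride_scheme == "table1") c(1L, 2L, 2L) else c(2L, 2L, 2L)

  with_local_seed(seed, {
    stem <- list(w = draw(c(7L, 7L, 7L, 1L, channels[["stem"]])),
                 b = numeric(channels[["stem"]]),
                 stride = stem_stride,
                 pool_kernel = c(3L, 3L, 3L), pool_stride = c(2L, 2L, 2L))
    module1 <- lapply(1:3, function(i)
      make_block(if (i == 1L) channels[["stem"]] else channels[["module1"]],
                 channels[["module1"]], width[1], c(1L, 1L, 1L)))
    module2 <- lapply(1:4, function(i)
      make_block(if (i == 1L) channels[["module1"]] else channels[["module2"]],
                 channels[["module2"]], width[2],
                 if (i == 1L) c(2L, 2L, 2L) else c(1L, 1L, 1L)))
    structure(list(seed = as.integer(seed), init_scheme = init_scheme,
                   stride_scheme = stride_scheme, channels = channels,
                   bottleneck_width = width, stem = stem,
                   module1 = module1, module2 = module2),
              class = "extractor_params")
  })
}

#' @export
print.extractor_params <- function(x, ...) {
  cat("<extractor_params> seed", x$seed, "scheme", x$init_scheme,
      "strides", x$stride_scheme, "\n  channels:",
      paste(names(x$channels), x$channels, sep = "=", collapse = ", "),
      "\n  blocks: module1 =", length(x$module1),
      ", module2 =", length(x$module2), "\n")
  invisible(x)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

as_tensor4d <- function(x) {
  if (inherits(x, "volume")) x <- x$data
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected a 3D volume or 4D feature tensor")
  x
}

#' 3D convolution with "same" padding
#'
#' Thin wrapper over the compiled kernel. Input is a `(x, y, z, channel)`
#' array, weights `(kx, ky, kz, c_in, c_out)`; output spatial size is
#' `ceil(in / stride)` per axis.
#'
#' @param x 4D input array.
#' @param w 5D weight array.
#' @param bias Per-output-channel bias (default zeros).
#' @param stride Length-3 (or scalar) positive integer stride.
#' @return 4D output array.
#' @export
conv3d <- function(x, w, bias = NULL, stride = 1L) {
  x <- as_tensor4d(x)
  stride <- as.integer(rep(stride, length.out = 3L))
  bias <- bias %||% numeric(dim(w)[5])
  cpp_conv3d(x, w, as.numeric(bias), stride)
}

#' 3D average pooling with "same" padding
#'
#' Padded voxels are excluded from the mean, so constant inputs are preserved.
#'
#' @param x 4D input array.
#' @param kernel Length-3 (or scalar) window size.
#' @param stride Length-3 (or scalar) stride.
#' @return 4D output array.
#' @export
avgpool3d <- function(x, kernel = 3L, stride = 2L) {
  x <- as_tensor4d(x)
  cpp_avgpool3d(x, as.integer(rep(kernel, length.out = 3L)),
                as.integer(rep(stride, length.out = 3L)))
}

#' Stem convolution-pooling layer
#'
#' The first stage of the extractor: 7x7x7 convolution, ReLU, then 3x3x3
#' average pooling. For a 224x224x128 input under the default stride scheme
#' the output is 112x56x32 with `channels["stem"]` channels.
#'
#' @param x 3D array or [volume()] (single channel).
#' @param p An [init_extractor()] parameter set.
#' @return 4D feature tensor.
#' @export
conv_pool_stem <- function(x, p) {
  stopifnot(inherits(p, "extractor_params"))
  x <- as_tensor4d(x)
  if (dim(x)[4] != 1L) stop("stem expects a single-channel input")
  if (any(dim(x)[1:3] < 1L)) stop("degenerate input shape")
  h <- relu(conv3d(x, p$stem$w, p$stem$b, p$stem$stride))
  avgpool3d(h, p$stem$pool_kernel, p$stem$pool_stride)
}

#' Apply one bottleneck residual block
#'
#' `out = relu(shortcut(x) + conv1x1(relu(conv3x3(relu(conv1x1(x))))))`, with
#' a 1x1x1 projection shortcut when the channel count or spatial shape
#' changes and the identity otherwise.
#'
#' @param x 4D input tensor whose channel count matches the block.
#' @param block One element of `p$module1` / `p$module2`.
#' @return 4D output tensor.
#' @export
bottleneck_block <- function(x, block) {
  x <- as_tensor4d(x)
  if (dim(x)[4] != dim(block$w1)[4])
    stop("channel mismatch: input has ", dim(x)[4], " channels, block expects ",
         dim(block$w1)[4])
  h <- relu(conv3d(x, block$w1, block$b1, 1L))
  h <- relu(conv3d(h, block$w2, block$b2, block$stride))
  h <- conv3d(h, block$w3, block$b3, 1L)
  s <- if (is.null(block$proj)) x
       else conv3d(x, block$proj, block$bproj, block$stride)
  relu(h + s)
}

run_module <- function(x, blocks) {
  for (b in blocks) x <- bottleneck_block(x, b)
  x
}

#' Global average pooling
#'
#' Reduces a `(x, y, z, channel)` tensor to one mean per channel.
#'
#' @param x 4D feature tensor.
#' @return Numeric vector of length `dim(x)[4]`.
#' @export
global_avg_pool <- function(x) {
  x <- as_tensor4d(x)
  d <- dim(x)
  colMeans(matrix(x, prod(d[1:3]), d[4]))
}

#' Extract the shallow/deep feature pair from one volume
#'
#' Runs the frozen backbone: `x_d` is the global average pool of residual
#' module 1 applied to the stem output; `x_e` pools residual module 2 applied
#' to module 1's (pre-pool) tensor. With full-width parameters the lengths
#' are 256 and 512.
#'
#' @param x 3D array or [volume()], already preprocessed.
#' @param p An [init_extractor()] parameter set.
#' @return List with numeric vectors `x_d` and `x_e`.
#' @export
extract_features <- function(x, p) {
  stopifnot(inherits(p, "extractor_params"))
  base <- conv_pool_stem(x, p)
  t1 <- run_module(base, p$module1)
  x_d <- global_avg_pool(t1)
  t2 <- run_module(t1, p$module2)
  x_e <- global_avg_pool(t2)
  if (!all(is.finite(x_d)) || !all(is.finite(x_e)))
    stop("non-finite feature values")
  list(x_d = x_d, x_e = x_e)
}
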