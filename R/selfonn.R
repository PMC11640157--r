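# Generative-neuron (Self-ONN) layers.
#
# A generative neuron replaces the fixed linear kernel of a convolutional
# neuron with a learned truncated MacLaurin series: the layer applies a
# separate kernel to each integer power x, x^2, ..., x^q of its input and
# sums the results.  q = 1 recovers an ordinary convolution.

#' Describe one Self-ONN layer
#'
#' A `selfonn_layer_spec` records the shape and Taylor order of a single
#' generative-neuron layer.  The trainable parameter count of such a layer
#' is `q * in_channels * out_channels * kernel_size^2` plus `out_channels`
#' bias terms when `has_bias` is `TRUE`.
#'
#' @param in_channels,out_channels Positive integers.
#' @param kernel_size Positive odd integer, spatial kernel support.
#' @param q Positive integer, order of the truncated MacLaurin series.
#'   `q = 1` makes the layer an ordinary cross-correlation.
#' @param stride Positive integer stride.
#' @param padding Non-negative integer zero-padding.
#' @param has_bias Logical, whether the layer owns a per-output-channel
#'   additive constant (the series' zeroth-order coefficient).
#' @return An object of class `selfonn_layer_spec`.
#' @examples
#' sp <- selfonn_layer_spec(1, 2, kernel_size = 3, q = 3)
#' selfonn_param_count(sp)  # 3*1*2*9 + 2 = 56
#' @export
selfonn_layer_spec <- function(in_channels, out_channels, kernel_size = 3L,
                               q = 3L, stride = 1L, padding = 0L,
                               has_bias = TRUE) {
  stopifnot(in_channels >= 1, out_channels >= 1, kernel_size >= 1,
            stride >= 1, padding >= 0)
  if (q < 1) stop("Taylor order q must be >= 1", call. = FALSE)
  if (kernel_size %% 2 == 0) stop("kernel_size must be odd", call. = FALSE)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel_size = as.integer(kernel_size),
                 q = as.integer(q),
                 stride = as.integer(stride),
                 padding = as.integer(padding),
                 has_bias = isTRUE(has_bias)),
            class = "selfonn_layer_spec")
}

#' Closed-form trainable parameter count of a Self-ONN layer
#' @param spec A [selfonn_layer_spec()].
#' @return Integer scalar.
#' @export
selfonn_param_count <- function(spec) {
  stopifnot(inherits(spec, "selfonn_layer_spec"))
  as.integer(spec$q * spec$in_channels * spec$out_channels *
               spec$kernel_size^2 +
               if (spec$has_bias) spec$out_channels else 0L)
}

#' Create (and initialise) Taylor coefficients for a Self-ONN layer
#'
#' `weights` has shape `(q, out_channels, in_channels, k, k)`: element
#' `[p, o, i, u, v]` multiplies the p-th power of input channel `i` at
#' kernel offset `(u, v)` and contributes to output channel `o`.  `bias`
#' is the shared zeroth-order constant per output channel.  Initialisation
#' is uniform on `[-a, a]` with `a = 1 / sqrt(in_channels * k^2 * q)`, a
#' variance-scaled range that keeps the power series stable for inputs in
#' `[-1, 1]`.
#'
#' @param spec A [selfonn_layer_spec()].
#' @param seed Optional integer seed for reproducible initialisation.
#' @param init `"uniform"` (default) or `"zeros"`.
#' @return An object of class `taylor_coefficients` with fields `weights`
#'   and `bias` (`NULL` when the spec has no bias).
#' @export
taylor_coefficients <- function(spec, seed = NULL,
                                init = c("uniform", "zeros")) {
  stopifnot(inherits(spec, "selfonn_layer_spec"))
  init <- match.arg(init)
  k <- spec$kernel_size
  dims <- c(spec$q, spec$out_channels, spec$in_channels, k, k)
  n <- prod(dims)
  if (init == "zeros") {
    w <- array(0, dim = dims)
  } else {
    if (!is.null(seed)) set.seed(seed)
    a <- 1 / sqrt(spec$in_channels * k^2 * spec$q)
    w <- array(stats::runif(n, -a, a), dim = dims)
  }
  b <- if (spec$has_bias) numeric(spec$out_channels) else NULL
  structure(list(weights = w, bias = b), class = "taylor_coefficients")
}

validate_selfonn_args <- function(x, spec, coef) {
  if (!inherits(spec, "selfonn_layer_spec"))
    stop("spec must be a selfonn_layer_spec", call. = FALSE)
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("x must be a (channels, height, width) array", call. = FALSE)
  if (d[1L] != spec$in_channels)
    stop("input has ", d[1L], " channels but spec expects ",
         spec$in_channels, call. = FALSE)
  wd <- dim(coef$weights)
  k <- spec$kernel_size
  if (!identical(as.integer(wd),
                 c(spec$q, spec$out_channels, spec$in_channels, k, k)))
    stop("coefficient weights shape (", paste(wd, collapse = ","),
         ") does not match spec (", paste(
           c(spec$q, spec$out_channels, spec$in_channels, k, k),
           collapse = ","), ")", call. = FALSE)
  if (spec$has_bias && length(coef$bias) != spec$out_channels)
    stop("bias length does not match out_channels", call. = FALSE)
  if (!all(is.finite(coef$weights)))
    stop("non-finite Taylor coefficients", call. = FALSE)
  invisible(TRUE)
}

# Reorder public (q, out, in, k, k) weights into the internal im2col
# weight matrix with rows ordered (channel fastest, then power, then ky,
# then kx) to match the stacked-power input layout.
taylor_weight_matrix <- function(coef, spec) {
  w <- aperm(coef$weights, c(3L, 1L, 4L, 5L, 2L))  # (in, q, kh, kw, out)
  dim(w) <- c(spec$q * spec$in_channels * spec$kernel_size^2,
              spec$out_channels)
  w
}

matrix_to_taylor_weights <- function(Wm, spec) {
  k <- spec$kernel_size
  dim(Wm) <- c(spec$in_channels, spec$q, k, k, spec$out_channels)
  aperm(Wm, c(2L, 5L, 1L, 3L, 4L))
}

stack_powers <- function(x, q) {
  x <- as_nchw(x)
  d <- dim(x)
  xq <- array(0, dim = c(q * d[1L], d[2L], d[3L], d[4L]))
  xp <- x
  xq[seq_len(d[1L]), , , ] <- xp
  if (q > 1L) for (p in 2:q) {
    xp <- xp * x
    xq[(p - 1L) * d[1L] + seq_len(d[1L]), , , ] <- xp
  }
  xq
}

#' Self-ONN layer forward pass
#'
#' Computes, for every output position, `bias[o] + sum over powers p,
#' input channels i and kernel offsets (u, v) of
#' `weights[p, o, i, u, v] * x[i, ...]^p`, with zero padding outside the
#' input support: the pool operator of the general operational-neuron
#' formulation is summation, and the nodal operator raises the input to
#' integer powers weighted by per-power kernels.
#'
#' @param x A `(channels, height, width)` numeric array.
#' @param spec A [selfonn_layer_spec()].
#' @param coef A [taylor_coefficients()] matching `spec`.
#' @return A `(out_channels, H', W')` array.
#' @examples
#' sp <- selfonn_layer_spec(1, 1, kernel_size = 3, q = 1)
#' co <- taylor_coefficients(sp, init = "zeros")
#' co$weights[] <- 1
#' selfonn_forward(array(1, c(1, 3, 3)), sp, co)  # single value 9
#' @export
selfonn_forward <- function(x, spec, coef) {
  validate_selfonn_args(x, spec, coef)
  squeeze <- length(dim(x)) == 3L
  xq <- stack_powers(x, spec$q)
  Wm <- taylor_weight_matrix(coef, spec)
  res <- conv2d_forward(xq, Wm, coef$bias, spec$kernel_size, spec$stride,
                        spec$padding)
  out <- res$out
  if (squeeze) dim(out) <- dim(out)[1:3]
  out
}

#' Brute-force reference implementation of the Self-ONN forward pass
#'
#' Identical contract to [selfonn_forward()], computed with explicit
#' nested loops over output pixels, channels, kernel offsets and powers.
#' No vectorised shortcuts; intended as an independent oracle for tests.
#'
#' @inheritParams selfonn_forward
#' @return A `(out_channels, H', W')` array.
#' @export
selfonn_forward_bruteforce <- function(x, spec, coef) {
  validate_selfonn_args(x, spec, coef)
  if (length(dim(x)) == 4L) {
    if (dim(x)[4L] != 1L) stop("brute-force oracle takes a single image")
    dim(x) <- dim(x)[1:3]
  }
  d <- dim(x)
  k <- spec$kernel_size; s <- spec$stride; p <- spec$padding
  Ho <- conv_out_size(d[2L], k, s, p)
  Wo <- conv_out_size(d[3L], k, s, p)
  out <- array(0, dim = c(spec$out_channels, Ho, Wo))
  for (o in seq_len(spec$out_channels)) {
    for (oy in seq_len(Ho)) {
      for (ox in seq_len(Wo)) {
        acc <- if (spec$has_bias) coef$bias[o] else 0
        for (i in seq_len(spec$in_channels)) {
          for (u in seq_len(k)) {
            for (v in seq_len(k)) {
              iy <- (oy - 1L) * s + u - p
              ix <- (ox - 1L) * s + v - p
              if (iy >= 1L && iy <= d[2L] && ix >= 1L && ix <= d[3L]) {
                xv <- x[i, iy, ix]
                for (pw in seq_len(spec$q)) {
                  acc <- acc + coef$weights[pw, o, i, u, v] * xv^pw
                }
              }
            }
          }
        }
        out[o, oy, ox] <- acc
      }
    }
  }
  out
}

# Forward with cache, for use inside networks (4-D tensors).
selfonn_forward_train <- function(x, spec, Wm, b) {
  x <- as_nchw(x)
  xq <- stack_powers(x, spec$q)
  res <- conv2d_forward(xq, Wm, b, spec$kernel_size, spec$stride,
                        spec$padding)
  list(out = res$out, cache = list(conv = res$cache, x = x, q = spec$q,
                                   C = dim(x)[1L]))
}

selfonn_backward_train <- function(dY, spec, Wm, cache) {
  cb <- conv2d_backward(dY, Wm, cache$conv, has_bias = spec$has_bias)
  dxq <- cb$dx                                   # gradient w.r.t. stacked powers
  C <- cache$C
  x <- cache$x
  dx <- dxq[seq_len(C), , , , drop = FALSE]
  if (cache$q > 1L) {
    xp <- array(1, dim = dim(x))                 # x^(p-1)
    for (p in 2:cache$q) {
      xp <- xp * x
      dx <- dx + p * xp * dxq[(p - 1L) * C + seq_len(C), , , , drop = FALSE]
    }
  }
  list(dx = dx, dW = cb$dW, db = cb$db)
}
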