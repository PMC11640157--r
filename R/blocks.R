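# Self-ONN residual blocks.
#
# Two composite units built from generative-neuron layers.  Both follow
# every Self-ONN layer with a tanh activation, which also keeps the
# intermediate feature maps inside (-1, 1) so that the power series of
# any downstream Self-ONN layer stays well conditioned.

#' Parameters for a Self-ONN residual block
#'
#' The block maps `channels` input channels through a 3x3 Self-ONN layer
#' (to `mid_channels`), tanh, a 1x1 Self-ONN layer restoring `channels`,
#' tanh, and finally adds the original input through a residual link.
#' Spatial size is unchanged.  With all weights and biases zero the block
#' is exactly the identity.
#'
#' @param channels Input (= output) channel count.
#' @param mid_channels Channel count after the 3x3 layer; defaults to a
#'   4-fold channel reduction, `max(1, channels %/% 4)`.
#' @param q Taylor order of both Self-ONN layers.
#' @param seed Optional seed for weight initialisation.
#' @return An object of class `selfonn_resblock_params` (holds the block's
#'   network graph).
#' @export
selfonn_resblock_params <- function(channels,
                                    mid_channels = max(1L, channels %/% 4L),
                                    q = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nb <- net_builder()
  inp <- nb_add(nb, op_input())
  a <- nb_add(nb, op_selfonn(channels, mid_channels, 3L, q, pad = 1L), inp)
  a <- nb_add(nb, op_tanh(), a)
  b <- nb_add(nb, op_selfonn(mid_channels, channels, 1L, q, pad = 0L), a)
  b <- nb_add(nb, op_tanh(), b)
  out <- nb_add(nb, op_add(), c(b, inp))
  structure(list(net = nb_finish(nb, inp, out),
                 channels = as.integer(channels),
                 mid_channels = as.integer(mid_channels), q = as.integer(q)),
            class = "selfonn_resblock_params")
}

#' Self-ONN residual block forward pass
#'
#' @param x A `(channels, H, W)` numeric array.
#' @param params A [selfonn_resblock_params()] object.
#' @return A `(channels, H, W)` array.
#' @export
selfonn_resblock <- function(x, params) {
  stopifnot(inherits(params, "selfonn_resblock_params"))
  d <- dim(x)
  if (d[1L] != params$channels)
    stop("input has ", d[1L], " channels, block expects ", params$channels,
         call. = FALSE)
  squeeze <- length(d) == 3L
  out <- net_forward(params$net, as_nchw(x))$out
  if (squeeze) dim(out) <- dim(out)[1:3]
  out
}

#' Parameters for a Self-ONN Conv residual block
#'
#' Two parallel paths over the same input: (a) a 3x3 Self-ONN layer with
#' tanh followed by a 1x1 Self-ONN layer with tanh, and (b) a plain 3x3
#' convolution.  Both paths expand the channel count by `expansion` and
#' keep the spatial size; their outputs are combined elementwise
#' (`combine = "add"`, the default) or stacked along the channel axis
#' (`combine = "concat"`).
#'
#' @param channels Input channel count.
#' @param expansion Channel expansion factor of both paths (default 4).
#' @param q Taylor order of the Self-ONN layers.
#' @param combine `"add"` or `"concat"`.
#' @param seed Optional seed for weight initialisation.
#' @return An object of class `selfonn_conv_resblock_params`.
#' @export
selfonn_conv_resblock_params <- function(channels, expansion = 4L, q = 3L,
                                         combine = c("add", "concat"),
                                         seed = NULL) {
  combine <- match.arg(combine)
  if (!is.null(seed)) set.seed(seed)
  ec <- as.integer(expansion * channels)
  nb <- net_builder()
  inp <- nb_add(nb, op_input())
  a <- nb_add(nb, op_selfonn(channels, ec, 3L, q, pad = 1L), inp)
  a <- nb_add(nb, op_tanh(), a)
  a <- nb_add(nb, op_selfonn(ec, ec, 1L, q, pad = 0L), a)
  a_act <- nb_add(nb, op_tanh(), a)
  b <- nb_add(nb, op_conv(channels, ec, 3L, pad = 1L), inp)
  out <- nb_add(nb, if (combine == "add") op_add() else op_concat(),
                c(a_act, b))
  structure(list(net = nb_finish(nb, inp, out),
                 channels = as.integer(channels), expanded = ec,
                 q = as.integer(q), combine = combine,
                 selfonn_path_node = a_act),
            class = "selfonn_conv_resblock_params")
}

#' Self-ONN Conv residual block forward pass
#'
#' @param x A `(channels, H, W)` numeric array.
#' @param params A [selfonn_conv_resblock_params()] object.
#' @return A `(expansion * channels, H, W)` array (twice that many
#'   channels under `combine = "concat"`).
#' @export
selfonn_conv_resblock <- function(x, params) {
  stopifnot(inherits(params, "selfonn_conv_resblock_params"))
  d <- dim(x)
  if (d[1L] != params$channels)
    stop("input has ", d[1L], " channels, block expects ", params$channels,
         call. = FALSE)
  squeeze <- length(d) == 3L
  out <- net_forward(params$net, as_nchw(x))$out
  if (squeeze) dim(out) <- dim(out)[1:3]
  out
}
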