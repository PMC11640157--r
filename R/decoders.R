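# Decoder architectures: U-Net, nested U-Net (U-Net++), feature pyramid
# network, and the Self-ONN U-Net in which every decoder convolution unit
# is a generative-neuron layer followed by tanh.

#' Describe a decoder
#'
#' @param kind One of `"unet"`, `"unetpp"`, `"fpn"`, `"selfonn_unet"`.
#' @param decoder_channels Five positive integers, output channels of the
#'   five decoder blocks from the deepest (stride 32) upwards.
#' @param q Taylor order of the Self-ONN decoder units (used only for
#'   `kind = "selfonn_unet"`).
#' @param fpn_segmentation_channels Channels of the merged FPN map.
#' @param norm Normalisation inside plain convolution units: `"batch"`
#'   (default) or `"none"`.  Self-ONN units never use normalisation; tanh
#'   already bounds their activations.
#' @param activation Activation of the decoder units; defaults to
#'   `"relu"` for plain convolution units and `"tanh"` for Self-ONN
#'   units.  `"identity"` is accepted for architectural comparisons.
#' @param selfonn_bottleneck_only Logical; when `TRUE` only the deepest
#'   (bottleneck-side) decoder block uses Self-ONN units and the rest are
#'   plain convolutions.  Default `FALSE`: Self-ONN throughout.
#' @return An object of class `decoder_spec`.
#' @export
decoder_spec <- function(kind = c("unet", "unetpp", "fpn", "selfonn_unet"),
                         decoder_channels = c(256L, 128L, 64L, 32L, 16L),
                         q = 3L, fpn_segmentation_channels = 128L,
                         norm = NULL, activation = NULL,
                         selfonn_bottleneck_only = FALSE) {
  kind <- match.arg(kind)
  decoder_channels <- as.integer(decoder_channels)
  if (length(decoder_channels) != 5L || any(decoder_channels < 1L))
    stop("decoder_channels must be 5 positive integers", call. = FALSE)
  if (q < 1L) stop("q must be >= 1", call. = FALSE)
  if (is.null(norm)) norm <- "batch"
  if (is.null(activation))
    activation <- if (kind == "selfonn_unet") "tanh" else "relu"
  structure(list(kind = kind, decoder_channels = decoder_channels,
                 q = as.integer(q),
                 fpn_segmentation_channels =
                   as.integer(fpn_segmentation_channels),
                 norm = norm, activation = activation,
                 selfonn_bottleneck_only = isTRUE(selfonn_bottleneck_only)),
            class = "decoder_spec")
}

# One decoder convolution unit.  Plain flavour: bias-free conv + batch
# norm + activation (norm = "none" drops the norm and restores the conv
# bias).  Self-ONN flavour: biased generative-neuron layer + activation.
append_dec_unit <- function(nb, from, in_ch, out_ch, selfonn, dspec) {
  if (selfonn) {
    x <- nb_add(nb, op_selfonn(in_ch, out_ch, 3L, dspec$q, pad = 1L,
                               bias = TRUE), from)
  } else if (dspec$norm == "batch") {
    x <- nb_add(nb, op_conv(in_ch, out_ch, 3L, pad = 1L, bias = FALSE), from)
    x <- nb_add(nb, op_bn(out_ch), x)
  } else {
    x <- nb_add(nb, op_conv(in_ch, out_ch, 3L, pad = 1L, bias = TRUE), from)
  }
  act <- if (selfonn && dspec$activation == "relu") "tanh" else dspec$activation
  nb_add(nb, op_activation(act), x)
}

append_unet_decoder <- function(nb, stages, enc_ch, dspec, selfonn) {
  dc <- dspec$decoder_channels
  skips <- c(stages[4L], stages[3L], stages[2L], stages[1L], NA_integer_)
  skip_ch <- c(enc_ch[4L], enc_ch[3L], enc_ch[2L], enc_ch[1L], 0L)
  x <- stages[5L]
  in_ch <- enc_ch[5L]
  for (i in 1:5) {
    so <- selfonn && (!dspec$selfonn_bottleneck_only || i == 1L)
    x <- nb_add(nb, op_upsample(2L), x)
    if (!is.na(skips[i])) x <- nb_add(nb, op_concat(), c(x, skips[i]))
    tot <- in_ch + skip_ch[i]
    x <- append_dec_unit(nb, x, tot, dc[i], so, dspec)
    x <- append_dec_unit(nb, x, dc[i], dc[i], so, dspec)
    in_ch <- dc[i]
  }
  list(out = x, out_ch = dc[5L])
}

append_unetpp_decoder <- function(nb, stages, enc_ch, dspec) {
  dc <- dspec$decoder_channels
  # grid rows i = 0..4 follow the encoder stages (row 0 at stride 2);
  # row output widths reuse the deep-to-shallow decoder channels
  rowch <- c(dc[4L], dc[3L], dc[2L], dc[1L])
  node <- matrix(NA_integer_, nrow = 5L, ncol = 5L)
  chan <- matrix(0L, nrow = 5L, ncol = 5L)
  for (i in 0:4) {
    node[i + 1L, 1L] <- stages[i + 1L]
    chan[i + 1L, 1L] <- enc_ch[i + 1L]
  }
  for (j in 1:4) {
    for (i in 0:(4 - j)) {
      up <- nb_add(nb, op_upsample(2L), node[i + 2L, j])
      parts <- c(node[i + 1L, 1:j], up)
      tot <- sum(chan[i + 1L, 1:j]) + chan[i + 2L, j]
      x <- nb_add(nb, op_concat(), parts)
      x <- append_dec_unit(nb, x, tot, rowch[i + 1L], FALSE, dspec)
      x <- append_dec_unit(nb, x, rowch[i + 1L], rowch[i + 1L], FALSE, dspec)
      node[i + 1L, j + 1L] <- x
      chan[i + 1L, j + 1L] <- rowch[i + 1L]
    }
  }
  # final block back to full resolution, no skip available there
  x <- nb_add(nb, op_upsample(2L), node[1L, 5L])
  x <- append_dec_unit(nb, x, rowch[1L], dc[5L], FALSE, dspec)
  x <- append_dec_unit(nb, x, dc[5L], dc[5L], FALSE, dspec)
  list(out = x, out_ch = dc[5L])
}

append_fpn_decoder <- function(nb, stages, enc_ch, dspec) {
  pyr <- 256L
  seg <- dspec$fpn_segmentation_channels
  # lateral 1x1 projections, deepest first, top-down pathway by addition
  p <- nb_add(nb, op_conv(enc_ch[5L], pyr, 1L, pad = 0L), stages[5L])
  ps <- list(p)
  for (lv in 4:2) {
    up <- nb_add(nb, op_upsample(2L), ps[[length(ps)]])
    lat <- nb_add(nb, op_conv(enc_ch[lv], pyr, 1L, pad = 0L), stages[lv])
    ps[[length(ps) + 1L]] <- nb_add(nb, op_add(), c(up, lat))
  }
  # per-level prediction maps brought to the stride-4 grid
  factors <- c(8L, 4L, 2L, 1L)
  maps <- integer(4L)
  for (z in 1:4) {
    m <- append_dec_unit(nb, ps[[z]], pyr, seg, FALSE, dspec)
    if (factors[z] > 1L) m <- nb_add(nb, op_upsample(factors[z]), m)
    maps[z] <- m
  }
  merged <- nb_add(nb, op_concat(), maps)
  x <- append_dec_unit(nb, merged, 4L * seg, seg, FALSE, dspec)
  list(out = x, out_ch = seg, head_upsample = 4L)
}

#' Build a decoder for a given encoder
#'
#' Returns a description that [build_model()] splices onto the encoder's
#' feature maps.  `unet`: five upsampling blocks, each concatenating the
#' matching encoder skip and applying two convolution units; `unetpp`:
#' nested dense skip pathways over the same grid; `fpn`: lateral 1x1
#' projections, top-down upsampling, per-level prediction maps merged on
#' a common grid and 3x3-convolved; `selfonn_unet`: the unet topology
#' with every decoder convolution unit replaced by a Self-ONN layer
#' followed by tanh.
#'
#' @param spec A [decoder_spec()].
#' @param encoder_spec An [encoder_spec()] the decoder must match.
#' @return An object of class `sonnseg_decoder`.
#' @export
build_decoder <- function(spec, encoder_spec) {
  stopifnot(inherits(spec, "decoder_spec"),
            inherits(encoder_spec, "encoder_spec"))
  attach_fn <- switch(spec$kind,
    unet = function(nb, stages, enc_ch)
      append_unet_decoder(nb, stages, enc_ch, spec, selfonn = FALSE),
    selfonn_unet = function(nb, stages, enc_ch)
      append_unet_decoder(nb, stages, enc_ch, spec, selfonn = TRUE),
    unetpp = function(nb, stages, enc_ch)
      append_unetpp_decoder(nb, stages, enc_ch, spec),
    fpn = function(nb, stages, enc_ch)
      append_fpn_decoder(nb, stages, enc_ch, spec))
  structure(list(spec = spec, encoder_spec = encoder_spec,
                 attach = attach_fn),
            class = "sonnseg_decoder")
}
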