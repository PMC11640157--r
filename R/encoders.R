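# Multi-scale encoder backbones.
#
# Faithful re-implementations of the standard residual (ResNet) and
# densely connected (DenseNet) image classifiers as feature extractors:
# the classifier head is removed and the five feature maps at strides
# 2, 4, 8, 16 and 32 are exposed for the decoder's skip connections.
# A "tiny" family (< 100k parameters) exists for fast end-to-end tests.
# Convolutions inside these backbones are bias-free and followed by batch
# normalisation, exactly as in the reference classifiers, so parameter
# counts match the originals.

encoder_family_table <- function() {
  list(
    resnet18    = list(kind = "resnet", block = "basic",
                       depths = c(2L, 2L, 2L, 2L),
                       stage_channels = c(64L, 64L, 128L, 256L, 512L)),
    resnet50    = list(kind = "resnet", block = "bottleneck",
                       depths = c(3L, 4L, 6L, 3L),
                       stage_channels = c(64L, 256L, 512L, 1024L, 2048L)),
    resnet101   = list(kind = "resnet", block = "bottleneck",
                       depths = c(3L, 4L, 23L, 3L),
                       stage_channels = c(64L, 256L, 512L, 1024L, 2048L)),
    resnet152   = list(kind = "resnet", block = "bottleneck",
                       depths = c(3L, 8L, 36L, 3L),
                       stage_channels = c(64L, 256L, 512L, 1024L, 2048L)),
    densenet121 = list(kind = "densenet", growth = 32L, init_channels = 64L,
                       config = c(6L, 12L, 24L, 16L),
                       stage_channels = c(64L, 256L, 512L, 1024L, 1024L)),
    densenet161 = list(kind = "densenet", growth = 48L, init_channels = 96L,
                       config = c(6L, 12L, 36L, 24L),
                       stage_channels = c(96L, 384L, 768L, 2112L, 2208L)),
    densenet201 = list(kind = "densenet", growth = 32L, init_channels = 64L,
                       config = c(6L, 12L, 48L, 32L),
                       stage_channels = c(64L, 256L, 512L, 1792L, 1920L)),
    tiny        = list(kind = "tiny",
                       stage_channels = c(8L, 12L, 16L, 24L, 32L))
  )
}

#' Describe an encoder backbone
#'
#' @param family One of `"resnet18"`, `"resnet50"`, `"resnet101"`,
#'   `"resnet152"`, `"densenet121"`, `"densenet161"`, `"densenet201"` or
#'   `"tiny"` (a < 100k-parameter backbone for tests).
#' @param pretrained Logical; when `TRUE`, [build_encoder()] loads weights
#'   from `weights_file` and raises an error if the file is absent (the
#'   package never downloads anything).
#' @param in_channels Number of image channels (default 3).
#' @param weights_file Optional path to a locally stored weight file.
#' @param norm Normalisation inside the `tiny` family: `"batch"`
#'   (default) or `"none"` (plain biased convolutions; useful when batch
#'   statistics must not change between forward passes).  The named
#'   reference families always use batch normalisation.
#' @return An object of class `encoder_spec` with the family's
#'   `stage_channels` (feature channels at strides 2, 4, 8, 16, 32).
#' @export
encoder_spec <- function(family, pretrained = FALSE, in_channels = 3L,
                         weights_file = NULL, norm = c("batch", "none")) {
  tab <- encoder_family_table()
  norm <- match.arg(norm)
  if (!family %in% names(tab))
    stop("unknown encoder family '", family, "'; available: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  if (norm == "none" && family != "tiny")
    stop("norm = 'none' is only available for the tiny family",
         call. = FALSE)
  stopifnot(in_channels >= 1)
  structure(list(family = family, pretrained = isTRUE(pretrained),
                 in_channels = as.integer(in_channels),
                 stage_channels = tab[[family]]$stage_channels,
                 weights_file = weights_file, norm = norm),
            class = "encoder_spec")
}

# -- resnet pieces -----------------------------------------------------------

append_conv_bn <- function(nb, from, in_ch, out_ch, k, stride = 1L,
                           pad = (k - 1L) %/% 2L) {
  x <- nb_add(nb, op_conv(in_ch, out_ch, k, stride, pad, bias = FALSE), from)
  nb_add(nb, op_bn(out_ch), x)
}

append_basic_block <- function(nb, from, in_ch, out_ch, stride) {
  x <- append_conv_bn(nb, from, in_ch, out_ch, 3L, stride)
  x <- nb_add(nb, op_relu(), x)
  x <- append_conv_bn(nb, x, out_ch, out_ch, 3L)
  sc <- if (stride != 1L || in_ch != out_ch)
    append_conv_bn(nb, from, in_ch, out_ch, 1L, stride, pad = 0L) else from
  x <- nb_add(nb, op_add(), c(x, sc))
  nb_add(nb, op_relu(), x)
}

append_bottleneck_block <- function(nb, from, in_ch, mid_ch, stride) {
  out_ch <- 4L * mid_ch
  x <- append_conv_bn(nb, from, in_ch, mid_ch, 1L, pad = 0L)
  x <- nb_add(nb, op_relu(), x)
  x <- append_conv_bn(nb, x, mid_ch, mid_ch, 3L, stride)
  x <- nb_add(nb, op_relu(), x)
  x <- append_conv_bn(nb, x, mid_ch, out_ch, 1L, pad = 0L)
  sc <- if (stride != 1L || in_ch != out_ch)
    append_conv_bn(nb, from, in_ch, out_ch, 1L, stride, pad = 0L) else from
  x <- nb_add(nb, op_add(), c(x, sc))
  nb_add(nb, op_relu(), x)
}

append_resnet <- function(nb, inp, fam, in_channels) {
  x <- append_conv_bn(nb, inp, in_channels, 64L, 7L, 2L, 3L)
  s2 <- nb_add(nb, op_relu(), x)
  x <- nb_add(nb, op_maxpool(3L, 2L, 1L), s2)
  basic <- fam$block == "basic"
  widths <- c(64L, 128L, 256L, 512L)
  cur <- 64L
  stages <- c(s2, rep(NA_integer_, 4L))
  for (st in 1:4) {
    stride <- if (st == 1L) 1L else 2L
    for (bl in seq_len(fam$depths[st])) {
      if (basic) {
        x <- append_basic_block(nb, x, cur, widths[st],
                                if (bl == 1L) stride else 1L)
        cur <- widths[st]
      } else {
        x <- append_bottleneck_block(nb, x, cur, widths[st],
                                     if (bl == 1L) stride else 1L)
        cur <- 4L * widths[st]
      }
    }
    stages[st + 1L] <- x
  }
  stages
}

# -- densenet pieces ---------------------------------------------------------

append_dense_layer <- function(nb, from, in_ch, growth, bn_size = 4L) {
  x <- nb_add(nb, op_bn(in_ch), from)
  x <- nb_add(nb, op_relu(), x)
  x <- nb_add(nb, op_conv(in_ch, bn_size * growth, 1L, pad = 0L,
                          bias = FALSE), x)
  x <- nb_add(nb, op_bn(bn_size * growth), x)
  x <- nb_add(nb, op_relu(), x)
  x <- nb_add(nb, op_conv(bn_size * growth, growth, 3L, pad = 1L,
                          bias = FALSE), x)
  nb_add(nb, op_concat(), c(from, x))
}

append_densenet <- function(nb, inp, fam, in_channels) {
  x <- nb_add(nb, op_conv(in_channels, fam$init_channels, 7L, 2L, 3L,
                          bias = FALSE), inp)
  x <- nb_add(nb, op_bn(fam$init_channels), x)
  s2 <- nb_add(nb, op_relu(), x)
  x <- nb_add(nb, op_maxpool(3L, 2L, 1L), s2)
  cur <- fam$init_channels
  stages <- c(s2, rep(NA_integer_, 4L))
  for (bi in seq_along(fam$config)) {
    for (li in seq_len(fam$config[bi])) {
      x <- append_dense_layer(nb, x, cur, fam$growth)
      cur <- cur + fam$growth
    }
    if (bi < length(fam$config)) {
      stages[bi + 1L] <- x                  # skip taken before transition
      x <- nb_add(nb, op_bn(cur), x)
      x <- nb_add(nb, op_relu(), x)
      x <- nb_add(nb, op_conv(cur, cur %/% 2L, 1L, pad = 0L, bias = FALSE), x)
      x <- nb_add(nb, op_avgpool2(), x)
      cur <- cur %/% 2L
    } else {
      x <- nb_add(nb, op_bn(cur), x)        # final norm
      x <- nb_add(nb, op_relu(), x)
      stages[bi + 1L] <- x
    }
  }
  stages
}

append_tiny <- function(nb, inp, fam, in_channels, norm = "batch") {
  ch <- fam$stage_channels
  stages <- integer(5L)
  cur_ch <- in_channels
  x <- inp
  for (st in 1:5) {
    if (norm == "batch") {
      x <- nb_add(nb, op_conv(cur_ch, ch[st], 3L, 2L, 1L, bias = FALSE), x)
      x <- nb_add(nb, op_bn(ch[st]), x)
    } else {
      x <- nb_add(nb, op_conv(cur_ch, ch[st], 3L, 2L, 1L, bias = TRUE), x)
    }
    x <- nb_add(nb, op_relu(), x)
    stages[st] <- x
    cur_ch <- ch[st]
  }
  stages
}

append_encoder <- function(nb, inp, spec) {
  fam <- encoder_family_table()[[spec$family]]
  switch(fam$kind,
         resnet = append_resnet(nb, inp, fam, spec$in_channels),
         densenet = append_densenet(nb, inp, fam, spec$in_channels),
         tiny = append_tiny(nb, inp, fam, spec$in_channels,
                            norm = if (is.null(spec$norm)) "batch"
                                   else spec$norm))
}

#' Build a multi-scale feature extractor
#'
#' Instantiates the backbone described by an [encoder_spec()].  Given an
#' image whose height and width are divisible by 32, [encoder_forward()]
#' returns five feature maps at strides 2, 4, 8, 16 and 32 with the
#' family's `stage_channels`.
#'
#' @param spec An [encoder_spec()].
#' @param seed Optional seed for weight initialisation.
#' @return An object of class `sonnseg_encoder`.
#' @export
build_encoder <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "encoder_spec"))
  if (!is.null(seed)) set.seed(seed)
  nb <- net_builder()
  inp <- nb_add(nb, op_input())
  stages <- append_encoder(nb, inp, spec)
  net <- nb_finish(nb, inp, stages[5L], stages = stages)
  enc <- structure(list(net = net, spec = spec, stages = stages),
                   class = "sonnseg_encoder")
  if (spec$pretrained) {
    if (is.null(spec$weights_file) || !file.exists(spec$weights_file))
      stop("pretrained = TRUE but no local weights file is available; ",
           "weights are never downloaded automatically", call. = FALSE)
    params <- readRDS(spec$weights_file)
    enc$net <- net_set_params(enc$net, params)
  }
  enc
}

#' Run an encoder on an image
#'
#' @param encoder A `sonnseg_encoder` from [build_encoder()].
#' @param x A `(in_channels, H, W)` array with `H`, `W` divisible by 32.
#' @return A list of five `(C, H/s, W/s)` feature maps, s = 2, 4, 8, 16, 32.
#' @export
encoder_forward <- function(encoder, x) {
  stopifnot(inherits(encoder, "sonnseg_encoder"))
  d <- dim(as_nchw(x))
  if (d[1L] != encoder$spec$in_channels)
    stop("input has ", d[1L], " channels, encoder expects ",
         encoder$spec$in_channels, call. = FALSE)
  if (d[2L] %% 32L != 0L || d[3L] %% 32L != 0L)
    stop("input height and width must be divisible by 32, got ",
         d[2L], "x", d[3L], call. = FALSE)
  fw <- net_forward(encoder$net, x, outputs = encoder$stages)
  lapply(fw$out, function(v) {
    if (dim(v)[4L] == 1L) dim(v) <- dim(v)[1:3]
    v
  })
}
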