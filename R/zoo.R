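# Assembled segmentation models: encoder + decoder + two-channel SoftMax
# head, plus the reference configurations used for complexity analysis.

#' Describe a full segmentation model
#'
#' @param encoder An [encoder_spec()].
#' @param decoder A [decoder_spec()].
#' @param classes Number of output classes; 2 (foreground/background,
#'   foreground = channel 2) throughout this package.
#' @return An object of class `segmentation_model_spec`.
#' @export
segmentation_model_spec <- function(encoder, decoder, classes = 2L) {
  stopifnot(inherits(encoder, "encoder_spec"),
            inherits(decoder, "decoder_spec"), classes >= 1)
  structure(list(encoder = encoder, decoder = decoder,
                 classes = as.integer(classes)),
            class = "segmentation_model_spec")
}

#' Build a segmentation network
#'
#' Assembles encoder, decoder and head into one network.  The head is a
#' 1x1 convolution to `classes` channels (3x3 for the FPN decoder)
#' followed by a channelwise SoftMax, so the per-pixel class
#' probabilities sum to one.
#'
#' @param spec A [segmentation_model_spec()].
#' @param seed Optional seed for weight initialisation; fixing it makes
#'   construction and forward passes bit-reproducible.
#' @return An object of class `sonnseg_model`.
#' @export
build_model <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "segmentation_model_spec"))
  if (!is.null(seed)) set.seed(seed)
  nb <- net_builder()
  inp <- nb_add(nb, op_input())
  stages <- append_encoder(nb, inp, spec$encoder)
  dec <- spec$decoder
  att <- build_decoder(dec, spec$encoder)
  res <- att$attach(nb, stages, spec$encoder$stage_channels)
  head_k <- if (dec$kind == "fpn") 3L else 1L
  x <- nb_add(nb, op_conv(res$out_ch, spec$classes, head_k,
                          pad = (head_k - 1L) %/% 2L, bias = TRUE), res$out)
  if (!is.null(res$head_upsample))
    x <- nb_add(nb, op_upsample(res$head_upsample), x)
  logits <- x
  out <- nb_add(nb, op_softmax2(), x)
  net <- nb_finish(nb, inp, out, stages = stages)
  structure(list(net = net, spec = spec, logits_node = logits,
                 decoder_out_node = res$out, decoder_out_ch = res$out_ch),
            class = "sonnseg_model")
}

#' Forward pass of a segmentation model
#'
#' @param object A `sonnseg_model`.
#' @param image A `(in_channels, H, W)` array (a bare `(H, W)` matrix is
#'   promoted to one channel), values expected in `[-1, 1]` for Self-ONN
#'   decoders and `[0, 1]` for plain convolution decoders.
#' @param type `"prob"` for the `(classes, H, W)` probability array,
#'   `"mask"` for the binary foreground mask (argmax; exact ties resolve
#'   to background).
#' @param ... Unused.
#' @return Probability array or binary mask matrix.
#' @export
predict.sonnseg_model <- function(object, image, type = c("prob", "mask"),
                                  ...) {
  type <- match.arg(type)
  if (is.matrix(image)) dim(image) <- c(1L, dim(image))
  p <- net_forward(object$net, image)$out
  if (dim(p)[4L] == 1L) dim(p) <- dim(p)[1:3]
  if (type == "prob") return(p)
  fg <- p[dim(p)[1L], , ]
  bg <- p[1L, , ]
  (fg > bg) * 1L
}

#' Reference Self-ONN U-Net configurations
#'
#' Returns the `segmentation_model_spec` of the ResNet18- or
#' DenseNet201-encoder Self-ONN U-Net used for complexity analysis.
#'
#' Two decoder width sets are available.  `calibrated = FALSE` gives the
#' default halving widths 256/128/64/32/16.  `calibrated = TRUE`
#' (default) gives the table-matching configuration with decoder widths
#' 256/124/72/25/33, obtained by the documented calibration search of
#' [calibrate_decoder_channels()]: an exhaustive integer search over the
#' Taylor order and the five decoder widths for the configuration whose
#' trainable-parameter counts reproduce the published complexity figures
#' of both reference models simultaneously (20,622,065 and 49,546,289).
#' Both variants use q = 3, a biased 1x1 two-channel head and 3-channel
#' input.
#'
#' @param family `"resnet18"` or `"densenet201"`.
#' @param calibrated Logical, see above.
#' @param q Taylor order (default 3).
#' @return A [segmentation_model_spec()].
#' @export
reference_selfonn_unet_spec <- function(family = c("resnet18", "densenet201"),
                                        calibrated = TRUE, q = 3L) {
  family <- match.arg(family)
  dc <- if (calibrated) c(256L, 124L, 72L, 25L, 33L)
        else c(256L, 128L, 64L, 32L, 16L)
  segmentation_model_spec(
    encoder = encoder_spec(family, in_channels = 3L),
    decoder = decoder_spec("selfonn_unet", decoder_channels = dc, q = q),
    classes = 2L)
}

# Closed-form trainable-parameter count of a Self-ONN U-Net, used only by
# the calibration search (instantiating every candidate would be absurd).
# enc_params: encoder scalar count; enc_ch: its five stage channels.
selfonn_unet_param_formula <- function(enc_params, enc_ch, q, dc,
                                       classes = 2L) {
  ins <- c(enc_ch[5L] + enc_ch[4L], dc[1L] + enc_ch[3L], dc[2L] + enc_ch[2L],
           dc[3L] + enc_ch[1L], dc[4L])
  w <- sum(9 * q * ins * dc + 9 * q * dc * dc)
  b <- sum(2 * dc)
  head <- dc[5L] * classes + classes
  enc_params + w + b + head
}

#' Calibration search for the reference decoder widths
#'
#' Searches integer decoder widths (and optionally the Taylor order) for
#' a Self-ONN U-Net configuration whose trainable-parameter counts equal
#' the two published complexity figures for the ResNet18- and
#' DenseNet201-encoder models simultaneously.  The difference between the
#' two published counts constrains `q * (2944 d1 + 384 d2 + 192 d3)`
#' exactly (only the first three decoder blocks see encoder-dependent
#' skip channels), so the search enumerates `(d1, d2, d3)` on that
#' constraint surface and solves a quadratic for `(d4, d5)`.
#'
#' @param target_resnet18,target_densenet201 Target parameter counts.
#' @param q Taylor orders to try.
#' @param d1_range Candidate widths of the deepest decoder block.
#' @return A data frame of matching configurations (columns `q`,
#'   `d1`..`d5`), ordered by L1 distance from the default widths
#'   256/128/64/32/16.  Empty if nothing in the searched space matches.
#' @export
calibrate_decoder_channels <- function(target_resnet18 = 20622065,
                                       target_densenet201 = 49546289,
                                       q = 3L, d1_range = 8:400) {
  enc_r18 <- 11176512
  enc_d201 <- 18092928
  r18_ch <- encoder_family_table()$resnet18$stage_channels
  diff_target <- (target_densenet201 - enc_d201) -
                 (target_resnet18 - enc_r18)
  hits <- list()
  for (qq in q) {
    if (diff_target %% (9L * qq) != 0L) next
    K <- diff_target %/% (9L * qq)          # 2944 d1 + 384 d2 + 192 d3
    for (d1 in d1_range) {
      rem <- K - 2944 * d1
      if (rem < 384 + 192) next
      d2s <- seq_len(rem %/% 384)
      d3s <- (rem - 384 * d2s)
      ok <- d3s %% 192 == 0
      d2s <- d2s[ok]; d3s <- d3s[ok] %/% 192
      keep <- d3s >= 2
      d2s <- d2s[keep]; d3s <- d3s[keep]
      for (z in seq_along(d2s)) {
        d2 <- d2s[z]; d3 <- d3s[z]
        base <- 9 * qq * ((r18_ch[5L] + r18_ch[4L]) * d1 +
                          (d1 + r18_ch[3L]) * d2 + (d2 + r18_ch[2L]) * d3 +
                          d1^2 + d2^2 + d3^2) + 2 * (d1 + d2 + d3)
        R0 <- target_resnet18 - enc_r18 - base - 2L   # minus head bias
        if (R0 <= 0) next
        d4 <- 2:512
        cc <- R0 - 9 * qq * ((d3 + r18_ch[1L]) * d4 + d4^2) - 2 * d4
        d4 <- d4[cc > 0]; cc <- cc[cc > 0]
        if (!length(d4)) next
        A <- 9 * qq
        B <- 9 * qq * d4 + 2 + 2   # d5 bias + 2-channel 1x1 head weights
        disc <- B^2 + 4 * A * cc
        s <- floor(sqrt(disc) + 0.5)
        exact <- s * s == disc & (s - B) %% (2 * A) == 0
        d5 <- (s - B) %/% (2 * A)
        sel <- exact & d5 >= 2
        for (w in which(sel)) {
          hits[[length(hits) + 1L]] <-
            data.frame(q = qq, d1 = d1, d2 = d2, d3 = d3,
                       d4 = d4[w], d5 = d5[w])
        }
      }
    }
  }
  if (!length(hits))
    return(data.frame(q = integer(), d1 = integer(), d2 = integer(),
                      d3 = integer(), d4 = integer(), d5 = integer()))
  out <- do.call(rbind, hits)
  ref <- c(256, 128, 64, 32, 16)
  out$l1 <- abs(out$d1 - ref[1]) + abs(out$d2 - ref[2]) +
            abs(out$d3 - ref[3]) + abs(out$d4 - ref[4]) + abs(out$d5 - ref[5])
  out <- out[order(out$l1), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- serialisation ---------------------------------------------------------

#' Serialise a model spec to / from YAML
#'
#' @param spec A [segmentation_model_spec()].
#' @param path Optional file; when given the YAML is written there.
#' @return `model_spec_to_yaml`: the YAML string (invisibly when written
#'   to a file).  `model_spec_from_yaml`: the reconstructed spec.
#' @export
model_spec_to_yaml <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "segmentation_model_spec"))
  obj <- list(
    encoder = list(family = spec$encoder$family,
                   pretrained = spec$encoder$pretrained,
                   in_channels = spec$encoder$in_channels,
                   norm = spec$encoder$norm),
    decoder = list(kind = spec$decoder$kind,
                   decoder_channels = as.integer(spec$decoder$decoder_channels),
                   q = spec$decoder$q,
                   fpn_segmentation_channels =
                     spec$decoder$fpn_segmentation_channels,
                   norm = spec$decoder$norm,
                   activation = spec$decoder$activation,
                   selfonn_bottleneck_only =
                     spec$decoder$selfonn_bottleneck_only),
    classes = spec$classes)
  txt <- yaml::as.yaml(obj)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname model_spec_to_yaml
#' @param yaml_text YAML string (alternative to `path`).
#' @export
model_spec_from_yaml <- function(path = NULL, yaml_text = NULL) {
  obj <- if (!is.null(path)) yaml::read_yaml(path)
         else yaml::yaml.load(yaml_text)
  segmentation_model_spec(
    encoder = encoder_spec(obj$encoder$family,
                           pretrained = isTRUE(obj$encoder$pretrained),
                           in_channels = obj$encoder$in_channels,
                           norm = if (is.null(obj$encoder$norm)) "batch"
                                  else obj$encoder$norm),
    decoder = decoder_spec(obj$decoder$kind,
                           decoder_channels =
                             as.integer(obj$decoder$decoder_channels),
                           q = obj$decoder$q,
                           fpn_segmentation_channels =
                             obj$decoder$fpn_segmentation_channels,
                           norm = obj$decoder$norm,
                           activation = obj$decoder$activation,
                           selfonn_bottleneck_only =
                             isTRUE(obj$decoder$selfonn_bottleneck_only)),
    classes = obj$classes)
}

#' Save / load model weights together with the producing spec
#'
#' The checkpoint is a single file holding every trainable array, the
#' batch-norm running statistics, and the YAML spec that rebuilds the
#' architecture.
#'
#' @param model A `sonnseg_model`.
#' @param path Checkpoint file path.
#' @return `load_checkpoint` returns the rebuilt `sonnseg_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "sonnseg_model"))
  running <- list()
  for (i in seq_along(model$net$nodes)) {
    op <- model$net$nodes[[i]]$op
    if (op$type == "bn")
      running[[as.character(i)]] <- list(mean = op$running$mean,
                                         var = op$running$var)
  }
  saveRDS(list(spec_yaml = model_spec_to_yaml(model$spec),
               params = net_params(model$net), running = running),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  spec <- model_spec_from_yaml(yaml_text = ck$spec_yaml)
  model <- build_model(spec)
  model$net <- net_set_params(model$net, ck$params)
  for (nm in names(ck$running)) {
    i <- as.integer(nm)
    model$net$nodes[[i]]$op$running$mean <- ck$running[[nm]]$mean
    model$net$nodes[[i]]$op$running$var <- ck$running[[nm]]$var
  }
  model
}
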