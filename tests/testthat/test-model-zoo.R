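# Encoders, decoders, assembled models, parameter counting.

test_that("resnet18 exposes the reference feature pyramid", {
  enc <- build_encoder(encoder_spec("resnet18"), seed = 1)
  fm <- encoder_forward(enc, array(stats::runif(3 * 224 * 224), c(3, 224, 224)))
  chans <- vapply(fm, function(m) dim(m)[1], integer(1))
  sizes <- vapply(fm, function(m) dim(m)[2], integer(1))
  expect_equal(chans, c(64L, 64L, 128L, 256L, 512L))
  expect_equal(sizes, c(112L, 56L, 28L, 14L, 7L))
  expect_identical(count_parameters(enc), 11176512)
  expect_error(encoder_forward(enc, array(0, c(3, 100, 100))), "divisible")
  expect_error(encoder_spec("resnet19"), "unknown encoder family")
})

test_that("tiny encoder stays under 100k parameters with 5 stages", {
  enc <- build_encoder(encoder_spec("tiny", in_channels = 1), seed = 1)
  fm <- encoder_forward(enc, array(0, c(1, 64, 64)))
  expect_length(fm, 5L)
  expect_equal(vapply(fm, function(m) dim(m)[2], integer(1)),
               c(32L, 16L, 8L, 4L, 2L))
  expect_lt(count_parameters(enc), 100000)
})

test_that("pretrained weights are never downloaded silently", {
  sp <- encoder_spec("tiny", pretrained = TRUE, in_channels = 1)
  expect_error(build_encoder(sp), "weights")
})

test_that("every decoder kind maps 64x64 input to 64x64 2-class probabilities", {
  img <- array(stats::runif(64 * 64, -1, 1), c(1, 64, 64))
  for (kind in c("unet", "selfonn_unet", "unetpp", "fpn")) {
    m <- build_model(tiny_model_spec(kind, q = 2), seed = 3)
    p <- predict(m, img)
    expect_equal(dim(p), c(2L, 64L, 64L), info = kind)
    expect_lt(max(abs(p[1, , ] + p[2, , ] - 1)), 1e-6)
  }
})

test_that("fpn merged map carries fpn_segmentation_channels channels", {
  m <- build_model(tiny_model_spec("fpn"), seed = 4)
  fw <- sonnseg:::net_forward(m$net, array(0, c(1, 64, 64, 1)),
                              outputs = m$decoder_out_node)
  expect_equal(dim(fw$out[[1]])[1], 16L)   # the spec used in tiny_model_spec
  expect_equal(m$decoder_out_ch, 16L)
})

test_that("construction and forward are bit-reproducible under a fixed seed", {
  img <- array(stats::runif(64 * 64, -1, 1), c(1, 64, 64))
  m1 <- build_model(tiny_model_spec("selfonn_unet"), seed = 42)
  m2 <- build_model(tiny_model_spec("selfonn_unet"), seed = 42)
  expect_identical(predict(m1, img), predict(m2, img))
})

test_that("selfonn_unet with q = 1 matches unet with mapped weights", {
  # both decoders built without normalisation and with identity
  # activation, so the comparison is at pre-activation level
  sp_conv <- tiny_model_spec("unet", norm = "none", activation = "identity")
  sp_onn <- tiny_model_spec("selfonn_unet", q = 1, norm = "none",
                            activation = "identity")
  mc <- build_model(sp_conv, seed = 7)
  mo <- build_model(sp_onn, seed = 8)
  # same node layout; q = 1 Self-ONN kernels are plain kernels
  mo$net <- sonnseg:::net_set_params(mo$net,
                                    sonnseg:::net_params(mc$net))
  img <- array(stats::runif(64 * 64, -1, 1), c(1, 64, 64))
  pc <- sonnseg:::net_forward(mc$net, sonnseg:::as_nchw(img),
                              outputs = mc$logits_node)$out[[1]]
  po <- sonnseg:::net_forward(mo$net, sonnseg:::as_nchw(img),
                              outputs = mo$logits_node)$out[[1]]
  expect_lt(max(abs(pc - po)), 1e-5)
})

test_that("doubling q adds exactly the per-power kernel count", {
  n1 <- count_parameters(build_model(tiny_model_spec("selfonn_unet", q = 2),
                                     seed = 1))
  n2 <- count_parameters(build_model(tiny_model_spec("selfonn_unet", q = 4),
                                     seed = 1))
  # per-power kernel count of the decoder: sum over its ten 3x3 units
  enc_ch <- encoder_spec("tiny", in_channels = 1)$stage_channels
  dc <- c(24L, 16L, 12L, 8L, 8L)
  ins <- c(enc_ch[5] + enc_ch[4], dc[1] + enc_ch[3], dc[2] + enc_ch[2],
           dc[3] + enc_ch[1], dc[4])
  per_power <- sum(9 * ins * dc + 9 * dc * dc)
  expect_identical(n2 - n1, 2 * per_power)
})

test_that("five-step training on a phantom batch stays finite", {
  vols <- tiny_phantoms()
  sl <- prepare_stage_slices(vols[1], "liver")
  n <- length(sl)
  m <- build_model(tiny_model_spec("selfonn_unet"), seed = 5)
  cfg <- train_config(learning_rate = 1e-3, max_epochs = 5, batch_size = 2,
                      early_stop_patience = 4, seed = 5)
  r <- train_model(m, sl[seq_len(n - 2L)], sl[(n - 1L):n], cfg,
                   max_steps = 5)
  expect_equal(r$steps_run, 5L)
  p <- predict(r$model, sl[[1]]$input)
  expect_true(all(is.finite(p)))
})

test_that("model specs round-trip through YAML and checkpoints", {
  sp <- tiny_model_spec("selfonn_unet", q = 2)
  y <- model_spec_to_yaml(sp)
  sp2 <- model_spec_from_yaml(yaml_text = y)
  expect_equal(sp2$decoder$decoder_channels, sp$decoder$decoder_channels)
  expect_equal(sp2$decoder$q, 2L)
  expect_equal(sp2$encoder$family, "tiny")

  m <- build_model(sp, seed = 9)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m, ck)
  m2 <- load_checkpoint(ck)
  img <- array(stats::runif(64 * 64, -1, 1), c(1, 64, 64))
  expect_identical(predict(m, img), predict(m2, img))
})

test_that("reference configurations reproduce the published complexity", {
  m <- build_model(reference_selfonn_unet_spec("resnet18"), seed = 1)
  expect_identical(count_parameters(m), 20622065)
  rm(m); gc(FALSE)
  m <- build_model(reference_selfonn_unet_spec("densenet201"), seed = 1)
  expect_identical(count_parameters(m), 49546289)
  rm(m); gc(FALSE)
})

test_that("calibration search recovers the recorded decoder widths", {
  # restricted to the canonical Taylor order and deep width for speed
  hits <- calibrate_decoder_channels(q = 3L, d1_range = 250:262)
  expect_true(nrow(hits) >= 1)
  expect_equal(unlist(hits[1, c("d1", "d2", "d3", "d4", "d5")],
                      use.names = FALSE),
               c(256, 124, 72, 25, 33))
})
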