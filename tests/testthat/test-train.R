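# Fold protocol, early stopping, training loop behaviour.

test_that("5-fold split of 100 volumes gives 20/16/64 per fold", {
  ids <- paste0("v", 1:100)
  fs <- make_folds(ids, 5, seed = 3)
  for (f in fs) {
    expect_length(f$test_ids, 20L)
    expect_length(f$val_ids, 16L)
    expect_length(f$train_ids, 64L)
    expect_length(intersect(f$train_ids, f$val_ids), 0L)
    expect_length(intersect(f$train_ids, f$test_ids), 0L)
    expect_length(intersect(f$val_ids, f$test_ids), 0L)
    expect_setequal(c(f$train_ids, f$val_ids, f$test_ids), ids)
  }
  # rotation: every id appears in exactly one test fold
  all_test <- unlist(lapply(fs, function(f) f$test_ids))
  expect_setequal(all_test, ids)
  expect_length(all_test, 100L)
  # determinism
  fs2 <- make_folds(ids, 5, seed = 3)
  expect_identical(lapply(fs, function(f) f$test_ids),
                   lapply(fs2, function(f) f$test_ids))
  expect_error(make_folds(paste0("v", 1:3), 5), "at least")
})

test_that("patience 1 with zero learning rate stops after exactly 2 epochs", {
  vols <- tiny_phantoms()
  sl <- prepare_stage_slices(vols[1], "liver")
  n <- length(sl)
  # normalisation-free model: with zero learning rate nothing evolves
  # between epochs (batch-norm running statistics would otherwise still
  # move the validation loss)
  sp <- segmentation_model_spec(
    encoder_spec("tiny", in_channels = 1, norm = "none"),
    decoder_spec("selfonn_unet", decoder_channels = c(24L, 16L, 12L, 8L, 8L)))
  m <- build_model(sp, seed = 1)
  cfg <- train_config(learning_rate = 0, max_epochs = 10, batch_size = 4,
                      early_stop_patience = 1, seed = 1)
  r <- train_model(m, sl[seq_len(n - 2L)], sl[(n - 1L):n], cfg)
  expect_equal(r$epochs_run, 2L)
})

test_that("training with identical seeds is bit-reproducible", {
  vols <- tiny_phantoms()
  sl <- prepare_stage_slices(vols[1], "liver")
  n <- length(sl)
  trn <- sl[seq_len(n - 2L)]; val <- sl[(n - 1L):n]
  cfg <- train_config(learning_rate = 1e-3, max_epochs = 3, batch_size = 2,
                      early_stop_patience = 2, seed = 17)
  r1 <- train_model(build_model(tiny_model_spec("selfonn_unet"), seed = 2),
                    trn, val, cfg, max_steps = 6)
  r2 <- train_model(build_model(tiny_model_spec("selfonn_unet"), seed = 2),
                    trn, val, cfg, max_steps = 6)
  expect_identical(sonnseg:::net_params(r1$model$net),
                   sonnseg:::net_params(r2$model$net))
})

test_that("returned weights are never worse than the best epoch seen", {
  vols <- tiny_phantoms()
  sl <- prepare_stage_slices(vols[1:2], "liver")
  nval <- max(2L, floor(0.2 * length(sl)))
  val <- sl[(length(sl) - nval + 1L):length(sl)]
  trn <- sl[seq_len(length(sl) - nval)]
  m <- build_model(tiny_model_spec("selfonn_unet"), seed = 4)
  cfg <- train_config(learning_rate = 1e-3, max_epochs = 6, batch_size = 4,
                      early_stop_patience = 3, seed = 4)
  r <- train_model(m, trn, val, cfg)
  expect_equal(r$best_val, min(r$history$val_loss), tolerance = 1e-12)
  # re-evaluating the returned weights reproduces the best epoch's loss
  revl <- sonnseg:::validation_loss(r$model, val, cfg$batch_size)
  expect_equal(revl, r$best_val, tolerance = 1e-8)
  # dice loss decreased over training
  expect_lt(r$history$train_loss[nrow(r$history)], r$history$train_loss[1])
})

test_that("evaluation driver scores oracle and degenerate models correctly", {
  vol <- tiny_phantoms()[[3]]
  slices <- suppressMessages(volume_to_slices(
    rescale_to_255(hu_window(vol)), keep_empty = FALSE))
  ev <- evaluate_fold(oracle_from_labels(vol$labels, "liver"),
                      oracle_from_labels(vol$labels, "tumor"), slices)
  expect_equal(unname(ev$liver$mean), rep(1, 3))
  expect_equal(unname(ev$tumor$mean), rep(1, 3))
  expect_equal(ev$tumor$zero_dice_count, 0L)

  # stage-1 oracle + all-background tumor model: every tumor-bearing
  # slice scores 0 and lands in the zero-dice count
  ev0 <- evaluate_fold(oracle_from_labels(vol$labels, "liver"),
                       function(im) matrix(0, nrow(im), ncol(im)), slices)
  n_tum <- sum(vapply(slices, function(s) sum(s$tumor_mask) > 0, logical(1)))
  expect_gt(n_tum, 0L)
  expect_equal(ev0$tumor$zero_dice_count, n_tum)
})
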