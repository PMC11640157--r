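# Training loop, k-fold cross-validation protocol, early stopping and
# the evaluation driver.

#' Training configuration
#'
#' Defaults follow the segmentation training protocol: Adam with betas
#' (0.9, 0.999), learning rate 1e-4, batch size 8, at most 50 epochs,
#' early stopping after 10 epochs without validation improvement, and a
#' learning-rate drop by factor 0.2 after 6 epochs of validation plateau.
#' The loss is the soft dice loss.
#'
#' @param learning_rate Positive Adam step size.
#' @param betas Adam momentum coefficients.
#' @param max_epochs Maximum training epochs.
#' @param batch_size Slices per optimizer step.
#' @param early_stop_patience Epochs without validation improvement
#'   before training stops.
#' @param lr_drop_factor Multiplicative learning-rate drop in (0, 1).
#' @param lr_plateau_patience Epochs of plateau before the drop.
#' @param seed Integer seed controlling shuffling and initialisation.
#' @param folds Number of cross-validation folds.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, betas = c(0.9, 0.999),
                         max_epochs = 50L, batch_size = 8L,
                         early_stop_patience = 10L, lr_drop_factor = 0.2,
                         lr_plateau_patience = 6L, seed = 1L, folds = 5L) {
  stopifnot(learning_rate >= 0, max_epochs >= 1, batch_size >= 1,
            early_stop_patience >= 1, lr_drop_factor > 0,
            lr_drop_factor < 1, lr_plateau_patience >= 1, folds >= 1)
  if (early_stop_patience >= max_epochs)
    stop("early_stop_patience must be below max_epochs", call. = FALSE)
  structure(list(learning_rate = learning_rate, betas = betas,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_drop_factor = lr_drop_factor,
                 lr_plateau_patience = as.integer(lr_plateau_patience),
                 seed = as.integer(seed), folds = as.integer(folds)),
            class = "train_config")
}

#' Cross-validation fold splits by volume
#'
#' Volumes (never slices) are shuffled deterministically and divided into
#' `k` rotating test blocks of ~20%; within each fold the last 20%
#' (floor) of the remaining training block becomes the validation set.
#' Every id appears in exactly one test fold; splitting by volume
#' prevents slices of one patient leaking across sets.
#'
#' @param volume_ids Character or integer vector of ids.
#' @param k Number of folds.
#' @param seed Shuffle seed.
#' @return List of `fold_split` objects with fields `fold_index` (0-based),
#'   `train_ids`, `val_ids`, `test_ids`.
#' @export
make_folds <- function(volume_ids, k = 5L, seed = 1L) {
  n <- length(volume_ids)
  if (n < k) stop("need at least k = ", k, " volumes, got ", n,
                  call. = FALSE)
  set.seed(seed)
  ids <- sample(volume_ids)
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-k] + 1L)
  lapply(seq_len(k), function(i) {
    test <- ids[starts[i]:ends[i]]
    rest <- ids[-(starts[i]:ends[i])]
    nval <- floor(0.2 * length(rest))
    val <- if (nval > 0L) rest[(length(rest) - nval + 1L):length(rest)]
           else character(0)
    train <- if (nval > 0L) rest[seq_len(length(rest) - nval)] else rest
    structure(list(fold_index = i - 1L, train_ids = train, val_ids = val,
                   test_ids = test),
              class = "fold_split")
  })
}

#' Build (input, target) slice pairs for one cascade stage
#'
#' Volumes are HU-windowed, rescaled to `[0, 255]` and scaled to the
#' model input range.  For the liver stage the input is the slice image
#' and the target the liver mask; for the tumor stage the input is the
#' ground-truth liver region of interest and the target the tumor mask.
#'
#' @param volumes List of [ct_volume()] objects with labels.
#' @param stage `"liver"` or `"tumor"`.
#' @param style Input scaling, `"selfonn"` (`[-1, 1]`) or `"conv"`.
#' @param keep_empty Keep liver-empty slices (default `FALSE`).
#' @param roi_mode ROI mode for the tumor stage.
#' @return List of training pairs `list(input, target, volume_id,
#'   slice_index)`.
#' @export
prepare_stage_slices <- function(volumes, stage = c("liver", "tumor"),
                                 style = "selfonn", keep_empty = FALSE,
                                 roi_mode = "multiply") {
  stage <- match.arg(stage)
  out <- list()
  for (vol in volumes) {
    v <- rescale_to_255(hu_window(vol))
    slices <- suppressMessages(volume_to_slices(v, keep_empty = keep_empty))
    for (sl in slices) {
      img <- scale_for_model(sl$image, style)
      if (stage == "liver") {
        input <- img
        target <- sl$liver_mask
      } else {
        input <- extract_roi(img, sl$liver_mask, roi_mode)
        target <- sl$tumor_mask
      }
      out[[length(out) + 1L]] <- list(input = input, target = target,
                                      volume_id = sl$volume_id,
                                      slice_index = sl$slice_index)
    }
  }
  out
}

stack_batch <- function(slices, idx) {
  first <- slices[[idx[1L]]]$input
  if (is.matrix(first)) dim(first) <- c(1L, dim(first))
  d <- dim(first)
  x <- array(0, dim = c(d, length(idx)))
  y <- array(0, dim = c(d[2L], d[3L], length(idx)))
  for (j in seq_along(idx)) {
    inp <- slices[[idx[j]]]$input
    if (is.matrix(inp)) dim(inp) <- c(1L, dim(inp))
    x[, , , j] <- inp
    y[, , j] <- slices[[idx[j]]]$target
  }
  list(x = x, y = y)
}

# mean soft dice loss of a probability tensor (2,H,W,N) vs targets (H,W,N)
batch_dice_loss <- function(p, y) {
  N <- dim(p)[4L]
  tot <- 0
  for (j in seq_len(N)) {
    tot <- tot + dice_loss(p[2L, , , j], y[, , j])
  }
  tot / N
}

batch_dice_grad <- function(p, y) {
  N <- dim(p)[4L]
  g <- array(0, dim = dim(p))
  for (j in seq_len(N)) {
    g[2L, , , j] <- dice_loss_grad(p[2L, , , j], y[, , j]) / N
  }
  g
}

validation_loss <- function(model, slices, batch_size = 8L) {
  n <- length(slices)
  tot <- 0
  at <- 1L
  while (at <= n) {
    idx <- at:min(n, at + batch_size - 1L)
    b <- stack_batch(slices, idx)
    p <- net_forward(model$net, b$x)$out
    for (j in seq_along(idx)) tot <- tot + dice_loss(p[2L, , , j], b$y[, , j])
    at <- at + batch_size
  }
  tot / n
}

#' Train a segmentation model with dice loss and early stopping
#'
#' Minimises the soft dice loss with Adam, monitors the validation loss
#' after every epoch, drops the learning rate by `lr_drop_factor` after
#' `lr_plateau_patience` epochs without improvement, stops after
#' `early_stop_patience` such epochs, and returns the weights of the best
#' validation epoch.  Fully seeded: identical config, data and seed give
#' identical final weights.
#'
#' @param model A `sonnseg_model`.
#' @param train_slices,val_slices Slice pair lists from
#'   [prepare_stage_slices()].
#' @param config A [train_config()].
#' @param max_steps Optional cap on total optimizer steps (used by the
#'   short end-to-end demonstrations); validation then runs at every
#'   epoch boundary and at the cap.
#' @param verbose Print per-epoch losses.
#' @return List with fields `model` (best-validation weights), `history`
#'   (data frame of epoch losses and learning rate), `best_val`,
#'   `epochs_run`, `steps_run`.
#' @export
train_model <- function(model, train_slices, val_slices, config,
                        max_steps = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "sonnseg_model"),
            inherits(config, "train_config"))
  if (!length(train_slices) || !length(val_slices))
    stop("empty training or validation set", call. = FALSE)
  set.seed(config$seed)
  params <- net_params(model$net)
  state <- adam_init(params)
  lr <- config$learning_rate
  best_val <- Inf
  best_params <- params
  best_running <- NULL
  wait <- 0L
  plateau <- 0L
  steps <- 0L
  hist <- list()
  n <- length(train_slices)
  done <- FALSE
  epoch <- 0L
  while (!done && epoch < config$max_epochs) {
    epoch <- epoch + 1L
    ord <- sample.int(n)
    at <- 1L
    ep_loss <- 0
    nb <- 0L
    while (at <= n) {
      idx <- ord[at:min(n, at + config$batch_size - 1L)]
      b <- stack_batch(train_slices, idx)
      fw <- net_forward(model$net, b$x, training = TRUE, keep_cache = TRUE)
      loss <- batch_dice_loss(fw$out, b$y)
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", epoch, ", step ",
             steps + 1L, "; inputs out of range or learning rate too high",
             call. = FALSE)
      dOut <- batch_dice_grad(fw$out, b$y)
      bw <- net_backward(model$net, fw, dOut)
      upd <- adam_step(params, bw$grads, state, lr, config$betas)
      params <- upd$params
      state <- upd$state
      model$net <- net_set_params(model$net, params)
      ep_loss <- ep_loss + loss
      nb <- nb + 1L
      steps <- steps + 1L
      at <- at + config$batch_size
      if (!is.null(max_steps) && steps >= max_steps) { done <- TRUE; break }
    }
    vl <- validation_loss(model, val_slices, config$batch_size)
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                val_loss = vl, lr = lr)
    if (verbose)
      message(sprintf("epoch %d  train %.4f  val %.4f  lr %.2g",
                      epoch, ep_loss / nb, vl, lr))
    if (vl < best_val) {
      best_val <- vl
      best_params <- params
      best_running <- snapshot_running(model$net)
      wait <- 0L
      plateau <- 0L
    } else {
      wait <- wait + 1L
      plateau <- plateau + 1L
      if (plateau >= config$lr_plateau_patience) {
        lr <- lr * config$lr_drop_factor
        plateau <- 0L
      }
      if (wait >= config$early_stop_patience) done <- TRUE
    }
  }
  model$net <- net_set_params(model$net, best_params)
  if (!is.null(best_running)) restore_running(model$net, best_running)
  list(model = model, history = do.call(rbind, hist), best_val = best_val,
       epochs_run = epoch, steps_run = steps)
}

snapshot_running <- function(net) {
  out <- list()
  for (i in seq_along(net$nodes)) {
    op <- net$nodes[[i]]$op
    if (op$type == "bn")
      out[[as.character(i)]] <- list(mean = op$running$mean,
                                     var = op$running$var)
  }
  out
}

restore_running <- function(net, snap) {
  for (nm in names(snap)) {
    i <- as.integer(nm)
    net$nodes[[i]]$op$running$mean <- snap[[nm]]$mean
    net$nodes[[i]]$op$running$var <- snap[[nm]]$var
  }
  invisible(net)
}

#' Evaluate a trained cascade on test slices
#'
#' Liver metrics compare the stage-1 prediction with the liver mask;
#' tumor metrics compare the full-cascade prediction (stage-2 on the ROI
#' built from the *predicted* liver mask) with the tumor mask.  Per-slice
#' DSC/IoU/accuracy are aggregated with 95% half-widths and zero-dice
#' counts.
#'
#' @param liver_model,tumor_model Trained `sonnseg_model`s (or functions,
#'   see [predict_mask()]).
#' @param slices Slice pairs: list of [volume_to_slices()] `slice_pair`s
#'   (images in `[0, 255]`).
#' @param style Input scaling of the models.
#' @param roi_mode,constrain_tumor_to_liver Cascade options.
#' @return List with `metric_report` fields `liver` and `tumor`.
#' @export
evaluate_fold <- function(liver_model, tumor_model, slices,
                          style = "selfonn", roi_mode = "multiply",
                          constrain_tumor_to_liver = FALSE) {
  cfg <- cascade_config(liver_model, tumor_model, roi_mode = roi_mode,
                        constrain_tumor_to_liver = constrain_tumor_to_liver)
  lrows <- list()
  trows <- list()
  for (sl in slices) {
    img <- scale_for_model(sl$image, style)
    res <- run_cascade(img, cfg, slice_index = sl$slice_index)
    cid <- paste0(sl$volume_id, ":", sl$slice_index)
    cl <- confusion(res$liver_mask, sl$liver_mask)
    lrows[[length(lrows) + 1L]] <-
      data.frame(sample_id = cid, dsc = dsc_score(cl), iou = iou_score(cl),
                 accuracy = accuracy_score(cl))
    ct <- confusion(res$tumor_mask, sl$tumor_mask)
    trows[[length(trows) + 1L]] <-
      data.frame(sample_id = cid, dsc = dsc_score(ct), iou = iou_score(ct),
                 accuracy = accuracy_score(ct))
  }
  list(liver = aggregate_metrics(do.call(rbind, lrows)),
       tumor = aggregate_metrics(do.call(rbind, trows)))
}

#' End-to-end phantom demonstration of the cascade
#'
#' Generates five 64x64 phantom volumes (12 slices each, 1-3 tumors),
#' trains a tiny Self-ONN U-Net for each cascade stage (three volumes for
#' training, one for validation, at most `max_steps` optimizer steps per
#' stage, Adam at 1e-3 -- a conventional from-scratch rate for such small
#' networks), and evaluates stage 1 and the full cascade on the held-out
#' fifth volume.
#'
#' @param seed Integer seed controlling phantom generation, weight
#'   initialisation and shuffling.
#' @param max_steps Optimizer steps per stage (default 200).
#' @param decoder_channels,q Tiny decoder configuration.
#' @return List with fields `liver` and `tumor` (`metric_report`s over
#'   the held-out slices), `liver_history`, `tumor_history`.
#' @export
tiny_cascade_experiment <- function(seed = 1L, max_steps = 200L,
                                    decoder_channels = c(24L, 16L, 12L, 8L, 8L),
                                    q = 3L) {
  pcfg <- phantom_config(seed = 100L + seed, n_volumes = 5L,
                         slices_per_volume = 12L, image_size = 64L,
                         n_tumors_range = c(1L, 3L))
  vols <- lapply(1:5, function(i) generate_phantom_volume(pcfg, i))
  mk <- function(s) build_model(segmentation_model_spec(
    encoder_spec("tiny", in_channels = 1L),
    decoder_spec("selfonn_unet", decoder_channels = decoder_channels,
                 q = q)), seed = s)
  cfg <- train_config(learning_rate = 1e-3, max_epochs = 40L,
                      batch_size = 4L, early_stop_patience = 10L,
                      seed = seed)
  rl <- train_model(mk(seed), prepare_stage_slices(vols[1:3], "liver"),
                    prepare_stage_slices(vols[4], "liver"), cfg,
                    max_steps = max_steps)
  rt <- train_model(mk(seed + 1L), prepare_stage_slices(vols[1:3], "tumor"),
                    prepare_stage_slices(vols[4], "tumor"), cfg,
                    max_steps = max_steps)
  tsl <- suppressMessages(volume_to_slices(
    rescale_to_255(hu_window(vols[[5]])), keep_empty = FALSE))
  ev <- evaluate_fold(rl$model, rt$model, tsl)
  list(liver = ev$liver, tumor = ev$tumor,
       liver_history = rl$history, tumor_history = rt$history)
}
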