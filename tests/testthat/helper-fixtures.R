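# Shared test fixtures and numerical helpers.  Everything is generated
# in code under fixed seeds; nothing is read from disk.

# central finite difference of f at selected coordinates of x
numeric_grad_at <- function(f, x, idx, eps = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

# check every parameter gradient of a network against central finite
# differences on a random scalar objective sum(out * dY)
expect_net_gradients <- function(net, x, eps = 1e-3, rel_tol = 1e-2,
                                 n_coords = 4L, seed = 99L) {
  set.seed(seed)
  fw <- sonnseg:::net_forward(net, x, training = TRUE, keep_cache = TRUE)
  dY <- array(stats::rnorm(length(fw$out)), dim(fw$out))
  bk <- sonnseg:::net_backward(net, fw, dY)
  params <- sonnseg:::net_params(net)
  for (nm in names(bk$grads)) {
    p <- params[[nm]]
    idx <- sample(length(p), min(n_coords, length(p)))
    fd <- numeric_grad_at(function(pv) {
      ps <- params; ps[[nm]] <- pv
      n2 <- sonnseg:::net_set_params(net, ps)
      sum(sonnseg:::net_forward(n2, x, training = TRUE)$out * dY)
    }, p, idx, eps)
    an <- as.vector(bk$grads[[nm]])[idx]
    scale <- pmax(abs(fd), abs(an), 1e-4)
    expect_lt(max(abs(fd - an) / scale), rel_tol,
              label = paste("gradient of", nm))
  }
  invisible(TRUE)
}

# one small shared phantom set for the cheaper tests
tiny_phantoms <- local({
  vols <- NULL
  function() {
    if (is.null(vols)) {
      cfg <- phantom_config(seed = 404L, n_volumes = 3L,
                            slices_per_volume = 8L, image_size = 64L,
                            n_tumors_range = c(1L, 2L))
      vols <<- lapply(1:3, function(i) generate_phantom_volume(cfg, i))
    }
    vols
  }
})

tiny_model_spec <- function(kind = "selfonn_unet", q = 3L,
                            in_channels = 1L,
                            dc = c(24L, 16L, 12L, 8L, 8L), ...) {
  segmentation_model_spec(
    encoder_spec("tiny", in_channels = in_channels),
    decoder_spec(kind, decoder_channels = dc, q = q,
                 fpn_segmentation_channels = 16L, ...))
}

# oracle "models" for cascade tests: functions that look up ground truth
oracle_from_labels <- function(labels, which = c("liver", "tumor")) {
  which <- match.arg(which)
  function(image, slice_index) {
    lab <- labels[, , slice_index + 1L]
    if (which == "liver") (lab >= 1L) * 1L else (lab == 2L) * 1L
  }
}
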