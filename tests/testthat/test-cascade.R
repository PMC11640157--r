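# Two-stage liver -> ROI -> tumor pipeline contracts.

const_prob_model <- function(p_bg, p_fg) {
  function(image) {
    d <- if (is.matrix(image)) dim(image) else dim(image)[2:3]
    out <- array(0, c(2, d))
    out[1, , ] <- p_bg
    out[2, , ] <- p_fg
    out
  }
}

test_that("predict_mask argmax and tie rule", {
  img <- matrix(0, 8, 8)
  expect_true(all(predict_mask(const_prob_model(0.9, 0.1), img) == 0))
  expect_true(all(predict_mask(const_prob_model(0.1, 0.9), img) == 1))
  # exact ties resolve to background
  expect_true(all(predict_mask(const_prob_model(0.5, 0.5), img) == 0))
})

test_that("extract_roi modes", {
  img <- matrix(5, 6, 6)
  expect_true(all(extract_roi(img, matrix(0, 6, 6)) == 0))
  expect_identical(extract_roi(img, matrix(1, 6, 6)), img)
  chk <- outer(1:6, 1:6, function(i, j) (i + j) %% 2)
  roi <- extract_roi(img, chk)
  expect_equal(sum(roi != 0), 18)
  expect_true(all(roi[chk == 1] == 5) && all(roi[chk == 0] == 0))
  cat2 <- extract_roi(img, chk, "concat_channel")
  expect_equal(dim(cat2), c(2L, 6L, 6L))
  expect_identical(cat2[1, , ], img)
  expect_identical(cat2[2, , ] * 1, chk * 1)
  expect_error(extract_roi(img, matrix(0, 3, 3)), "shapes")
})

test_that("oracle cascade reproduces phantom ground truth exactly", {
  vol <- tiny_phantoms()[[1]]
  pre <- rescale_to_255(hu_window(vol))
  pre$voxels <- scale_for_model(pre$voxels, "selfonn")
  cfg <- cascade_config(oracle_from_labels(vol$labels, "liver"),
                        oracle_from_labels(vol$labels, "tumor"))
  res <- run_cascade_volume(pre, cfg)
  expect_identical(res$liver_mask == 1L, vol$labels >= 1L)
  expect_identical(res$tumor_mask == 1L, vol$labels == 2L)
  # ROI zeroing invariant on every slice
  for (z in seq_len(dim(vol$voxels)[3])) {
    r <- res$per_slice[[z]]
    expect_true(all(r$roi_image[r$liver_mask == 0] == 0))
  }
})

test_that("empty liver mask forces an all-zero ROI", {
  img <- matrix(stats::runif(64), 8, 8)
  cfg <- cascade_config(function(im) matrix(0, 8, 8),
                        function(im) (im > 0.5) * 1)
  res <- run_cascade(img, cfg)
  expect_true(all(res$roi_image == 0))
  expect_true(all(res$tumor_mask == 0))
})

test_that("constrain_tumor_to_liver forces tumor inside liver", {
  img <- matrix(stats::runif(64), 8, 8)
  liver <- matrix(0, 8, 8); liver[3:6, 3:6] <- 1
  cfg <- cascade_config(function(im) liver,
                        function(im) matrix(1, 8, 8),   # everything "tumor"
                        constrain_tumor_to_liver = TRUE)
  res <- run_cascade(img, cfg)
  expect_true(all(res$tumor_mask[liver == 0] == 0))
  expect_lte(sum(res$tumor_mask), sum(res$liver_mask))
  # without the flag the stage-2 output passes through
  cfg2 <- cascade_config(function(im) liver, function(im) matrix(1, 8, 8))
  expect_true(any(run_cascade(img, cfg2)$tumor_mask[liver == 0] == 1))
})

test_that("trained-model cascade runs are deterministic", {
  m <- build_model(tiny_model_spec("selfonn_unet"), seed = 50)
  vol <- tiny_phantoms()[[2]]
  pre <- rescale_to_255(hu_window(vol))
  pre$voxels <- scale_for_model(pre$voxels, "selfonn")
  cfg <- cascade_config(m, m)
  r1 <- run_cascade_volume(pre, cfg)
  r2 <- run_cascade_volume(pre, cfg)
  expect_identical(r1$liver_mask, r2$liver_mask)
  expect_identical(r1$tumor_mask, r2$tumor_mask)
})
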