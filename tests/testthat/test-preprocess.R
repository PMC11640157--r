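# HU windowing, rescaling, slice extraction, NIfTI round trips.

test_that("hu_window clips to the liver window and is idempotent", {
  v <- ct_volume(array(c(-1000, 400, 2000, 150, -100, 0), c(1, 2, 3)))
  w <- hu_window(v)
  expect_equal(as.vector(w$voxels), c(-100, 400, 400, 150, -100, 0))
  expect_equal(hu_window(w)$voxels, w$voxels)
  expect_error(hu_window(v, lo = 10, hi = 10), "lo < hi")
})

test_that("rescale_to_255 maps window endpoints and midpoints as printed", {
  v <- ct_volume(array(c(-100, 400, 150, -100), c(1, 2, 2)))
  r <- rescale_to_255(hu_window(v))
  expect_equal(as.vector(r$voxels), c(0, 255, 127.5, 0))
  r8 <- rescale_to_255(hu_window(v), uint8 = TRUE)
  expect_equal(as.vector(r8$voxels), c(0, 255, 128, 0))
  # composition lands in [0, 255] for arbitrary volumes
  set.seed(8)
  v2 <- ct_volume(array(stats::rnorm(4 * 4 * 4, 100, 800), c(4, 4, 4)))
  r2 <- rescale_to_255(hu_window(v2))
  expect_true(all(r2$voxels >= 0 & r2$voxels <= 255))
})

test_that("slice extraction filters liver-empty slices and conserves counts", {
  lab <- array(0L, c(4, 4, 10))
  lab[2, 2, 4:8] <- 1L           # liver on slices 3..7 (0-based)
  lab[3, 3, 5] <- 2L             # one tumor pixel
  v <- ct_volume(array(0, c(4, 4, 10)), labels = lab)
  expect_message(sl <- volume_to_slices(v, keep_empty = FALSE), "kept 5")
  expect_length(sl, 5L)
  expect_equal(vapply(sl, function(s) s$slice_index, integer(1)), 3:7)
  expect_length(volume_to_slices(v, keep_empty = TRUE), 10L)
  sl_all <- volume_to_slices(v, keep_empty = TRUE)
  expect_equal(sum(vapply(sl_all, function(s) sum(s$liver_mask), numeric(1))),
               sum(lab >= 1))
  expect_equal(sum(vapply(sl_all, function(s) sum(s$tumor_mask), numeric(1))),
               sum(lab == 2))
  # tumor pixels are liver tissue: liver mask covers label-2 pixels
  expect_equal(sl_all[[5]]$liver_mask[3, 3], 1L)

  lab[1, 1, 1] <- 3L
  expect_error(ct_volume(array(0, c(4, 4, 10)), labels = lab), "0,1,2|\\{0")
  expect_error(volume_to_slices(ct_volume(array(0, c(2, 2, 2)))), "labels")
})

test_that("NIfTI write-read round trip is bit-exact", {
  set.seed(10)
  lab <- array(sample(0:2, 4 * 8 * 6, replace = TRUE), c(4, 8, 6))
  v <- ct_volume(array(stats::rnorm(4 * 8 * 6), c(4, 8, 6)),
                 spacing = c(0.8, 0.8, 2.5), labels = lab, id = "rt")
  vp <- tempfile(fileext = ".nii.gz")
  sp <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(v, vp, sp)
  v2 <- load_nifti(vp, sp)
  expect_identical(v2$voxels, v$voxels)
  expect_identical(v2$labels, v$labels)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  expect_error(load_nifti(tempfile(fileext = ".nii")), "not found")
})

test_that("2-D images are rejected by the loader", {
  img <- RNifti::asNifti(matrix(stats::rnorm(16), 4, 4))
  p <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, p)
  expect_error(load_nifti(p), "3-D")
})

test_that("model input scaling hits the advertised ranges", {
  img <- matrix(c(0, 127.5, 255), 1)
  expect_equal(as.vector(scale_for_model(img, "selfonn")), c(-1, 0, 1))
  expect_equal(as.vector(scale_for_model(img, "conv")), c(0, 0.5, 1))
})
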