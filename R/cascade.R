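# Two-stage inference: liver segmentation -> region-of-interest
# extraction -> tumor segmentation.
#
# The first network segments the liver on a CT slice; its binary mask is
# placed over the slice (elementwise product by default) so the second
# network searches for tumors only inside the liver region.

#' Predict a binary mask from a segmentation model
#'
#' Argmax over the two-channel SoftMax output; exact probability ties
#' resolve to background (conservative for lesion calling).  `model` may
#' also be a function for testing: it receives the image (and, from
#' [run_cascade_volume()], optionally the slice index) and returns either
#' a `(2, H, W)` probability array or a binary mask.
#'
#' @param model A `sonnseg_model` or a function.
#' @param image Input image, `(H, W)` matrix or `(C, H, W)` array.
#' @return Binary `(H, W)` mask matrix.
#' @export
predict_mask <- function(model, image) {
  if (is.function(model)) {
    r <- model(image)
    return(interpret_model_output(r))
  }
  stopifnot(inherits(model, "sonnseg_model"))
  predict(model, image, type = "mask")
}

interpret_model_output <- function(r) {
  d <- dim(r)
  if (!is.null(d) && length(d) == 3L && d[1L] == 2L) {
    return((r[2L, , ] > r[1L, , ]) * 1L)
  }
  (r > 0.5 | r == 1) * 1L   # already a mask
}

#' Extract the liver region of interest
#'
#' `multiply`: elementwise product of image and mask (the ROI is exactly
#' zero outside the liver).  `concat_channel`: stack `(image, mask)` as a
#' two-channel input.
#'
#' @param image `(H, W)` matrix.
#' @param liver_mask Binary `(H, W)` matrix.
#' @param roi_mode `"multiply"` or `"concat_channel"`.
#' @return `(H, W)` matrix (multiply) or `(2, H, W)` array (concat).
#' @export
extract_roi <- function(image, liver_mask,
                        roi_mode = c("multiply", "concat_channel")) {
  roi_mode <- match.arg(roi_mode)
  if (!identical(dim(image), dim(liver_mask)))
    stop("image and mask shapes differ", call. = FALSE)
  if (roi_mode == "multiply") return(image * liver_mask)
  out <- array(0, dim = c(2L, dim(image)))
  out[1L, , ] <- image
  out[2L, , ] <- liver_mask
  out
}

#' Cascade configuration
#'
#' @param liver_model,tumor_model `sonnseg_model` objects (or functions,
#'   see [predict_mask()]).
#' @param roi_mode `"multiply"` (default; matches placing the mask over
#'   the CT image) or `"concat_channel"`.
#' @param constrain_tumor_to_liver Logical; when `TRUE` the tumor mask is
#'   intersected with the liver mask after stage 2 (default `FALSE`).
#' @return An object of class `cascade_config`.
#' @export
cascade_config <- function(liver_model, tumor_model,
                           roi_mode = c("multiply", "concat_channel"),
                           constrain_tumor_to_liver = FALSE) {
  roi_mode <- match.arg(roi_mode)
  structure(list(liver_model = liver_model, tumor_model = tumor_model,
                 roi_mode = roi_mode,
                 constrain_tumor_to_liver =
                   isTRUE(constrain_tumor_to_liver)),
            class = "cascade_config")
}

#' Run the liver -> ROI -> tumor cascade on one slice
#'
#' @param image `(H, W)` matrix in the models' input range.
#' @param config A [cascade_config()].
#' @param slice_index Optional index forwarded to function-valued models
#'   that accept a second argument.
#' @return Object of class `cascade_result` with fields `liver_mask`,
#'   `roi_image`, `tumor_mask`.
#' @export
run_cascade <- function(image, config, slice_index = NULL) {
  stopifnot(inherits(config, "cascade_config"))
  liver <- call_stage(config$liver_model, image, slice_index)
  roi <- extract_roi(image, liver, config$roi_mode)
  tumor <- call_stage(config$tumor_model, roi, slice_index)
  if (config$constrain_tumor_to_liver) tumor <- tumor * liver
  structure(list(liver_mask = liver, roi_image = roi, tumor_mask = tumor),
            class = "cascade_result")
}

call_stage <- function(model, x, slice_index) {
  if (is.function(model) && length(formals(model)) >= 2L &&
      !is.null(slice_index)) {
    return(interpret_model_output(model(x, slice_index)))
  }
  predict_mask(model, x)
}

#' Run the cascade over every axial slice of a volume
#'
#' Slices are processed in index order; the per-slice masks are
#' reassembled into 3-D arrays of the volume's shape.
#'
#' @param volume A preprocessed [ct_volume()] whose voxel values are
#'   already in the models' input range.
#' @param config A [cascade_config()].
#' @return Object of class `cascade_volume_result` with fields
#'   `per_slice` (list of `cascade_result`), `liver_mask` and
#'   `tumor_mask` (3-D arrays).
#' @export
run_cascade_volume <- function(volume, config) {
  stopifnot(inherits(volume, "ct_volume"), inherits(config, "cascade_config"))
  d <- dim(volume$voxels)
  liver3 <- array(0L, dim = d)
  tumor3 <- array(0L, dim = d)
  per_slice <- vector("list", d[3L])
  for (z in seq_len(d[3L])) {
    res <- run_cascade(volume$voxels[, , z], config, slice_index = z - 1L)
    per_slice[[z]] <- res
    liver3[, , z] <- res$liver_mask
    tumor3[, , z] <- res$tumor_mask
  }
  structure(list(per_slice = per_slice, liver_mask = liver3,
                 tumor_mask = tumor3),
            class = "cascade_volume_result")
}

#' Write a per-slice overlay image of masks on a CT slice
#'
#' Renders the slice as grayscale and draws mask boundaries on top:
#' ground truth (if given) in green, the prediction in red.  Boundary
#' pixels are mask pixels with at least one non-mask 4-neighbour.
#'
#' @param image `(H, W)` matrix (any range; rescaled to `[0, 1]`).
#' @param pred_mask Binary prediction mask.
#' @param gt_mask Optional binary reference mask.
#' @param path Output PNG file.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(image, pred_mask, gt_mask = NULL, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for overlay export", call. = FALSE)
  rng <- range(image)
  g <- if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1])
       else image * 0
  rgb <- array(g, dim = c(dim(g), 3L))
  boundary <- function(m) {
    m <- m != 0
    d <- dim(m)
    inner <- m
    inner[2:d[1], ] <- inner[2:d[1], ] & m[1:(d[1] - 1), ]
    inner[1:(d[1] - 1), ] <- inner[1:(d[1] - 1), ] & m[2:d[1], ]
    inner[, 2:d[2]] <- inner[, 2:d[2]] & m[, 1:(d[2] - 1)]
    inner[, 1:(d[2] - 1)] <- inner[, 1:(d[2] - 1)] & m[, 2:d[2]]
    m & !inner
  }
  if (!is.null(gt_mask)) {
    b <- boundary(gt_mask)
    rgb[, , 1][b] <- 0; rgb[, , 2][b] <- 1; rgb[, , 3][b] <- 0
  }
  b <- boundary(pred_mask)
  rgb[, , 1][b] <- 1; rgb[, , 2][b] <- 0; rgb[, , 3][b] <- 0
  png::writePNG(rgb, path)
  invisible(path)
}
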