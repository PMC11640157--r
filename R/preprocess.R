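# CT volume handling: NIfTI I/O, Hounsfield-unit windowing, intensity
# rescaling and axial 3-D -> 2-D slice extraction.
#
# Hounsfield units (HU) are the calibrated CT attenuation scale (water 0,
# air about -1000).  Windowing to [-100, 400] keeps soft tissue / liver
# contrast and discards bone and air extremes before mapping to [0, 255].

#' Construct a CT volume
#'
#' @param voxels Real 3-D array in Hounsfield units.
#' @param spacing Three positive voxel spacings in mm.
#' @param affine 4x4 voxel-to-world matrix.
#' @param labels Optional integer 3-D array of the same shape with values
#'   in `{0, 1, 2}` (0 background, 1 liver, 2 tumor; tumor voxels are
#'   liver tissue).
#' @param id Volume identifier used in slice bookkeeping.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), affine = diag(4),
                      labels = NULL, id = "volume") {
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3-D array, got ", length(dim(voxels)),
         " dimensions", call. = FALSE)
  stopifnot(length(spacing) == 3L, all(spacing > 0),
            identical(dim(affine), c(4L, 4L)))
  if (!is.null(labels)) {
    if (!identical(dim(labels), dim(voxels)))
      stop("labels shape must equal voxels shape", call. = FALSE)
    bad <- setdiff(unique(as.vector(labels)), c(0, 1, 2))
    if (length(bad))
      stop("labels must take values in {0,1,2}; found ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 affine = affine, labels = labels, id = id),
            class = "ct_volume")
}

#' Load a NIfTI CT volume (and optional label volume)
#'
#' Reads `.nii` / `.nii.gz` with the orientation exactly as stored (no
#' reorientation); spacing and affine come from the header.
#'
#' @param path Image file.
#' @param label_path Optional segmentation file of the same shape.
#' @param id Volume identifier; defaults to the file name without
#'   extensions.
#' @return A [ct_volume()].
#' @export
load_nifti <- function(path, label_path = NULL, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  vox <- array(as.numeric(img), dim = dim(img))
  if (length(dim(vox)) != 3L)
    stop("expected a 3-D volume, got ", length(dim(vox)),
         " dimensions in ", path, call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  affine <- unclass(RNifti::xform(img))
  labels <- NULL
  if (!is.null(label_path)) {
    seg <- RNifti::readNifti(label_path)
    labels <- array(as.integer(round(as.numeric(seg))), dim = dim(seg))
  }
  if (is.null(id)) id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  ct_volume(vox, spacing = spacing, affine = affine, labels = labels,
            id = id)
}

#' Write a CT volume (and its labels) as NIfTI
#'
#' @param volume A [ct_volume()].
#' @param path Image file path (`.nii.gz`).
#' @param label_path Optional path for the label volume.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(volume, path, label_path = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  if (!is.null(label_path)) {
    if (is.null(volume$labels)) stop("volume has no labels", call. = FALSE)
    seg <- RNifti::asNifti(volume$labels)
    RNifti::pixdim(seg) <- volume$spacing
    RNifti::writeNifti(seg, label_path)
  }
  invisible(path)
}

#' Hounsfield-unit windowing
#'
#' Clips every voxel to `[lo, hi]`; labels are untouched.  Idempotent.
#'
#' @param volume A [ct_volume()].
#' @param lo,hi Window bounds in HU (default -100 and 400, the
#'   liver window).
#' @return The windowed [ct_volume()].
#' @export
hu_window <- function(volume, lo = -100, hi = 400) {
  stopifnot(inherits(volume, "ct_volume"))
  if (lo >= hi) stop("window requires lo < hi", call. = FALSE)
  volume$voxels <- pmin(pmax(volume$voxels, lo), hi)
  volume
}

#' Rescale a windowed volume to [0, 255]
#'
#' Maps `v` to `255 * (v - lo) / (hi - lo)`.  By default intensities stay
#' real-valued; `uint8 = TRUE` rounds half away from zero to integers.
#'
#' @inheritParams hu_window
#' @param uint8 Logical, quantise to integers.
#' @return The rescaled [ct_volume()].
#' @export
rescale_to_255 <- function(volume, lo = -100, hi = 400, uint8 = FALSE) {
  stopifnot(inherits(volume, "ct_volume"))
  if (lo >= hi) stop("degenerate window", call. = FALSE)
  v <- 255 * (volume$voxels - lo) / (hi - lo)
  if (uint8) v <- floor(v + 0.5)   # round half away from zero (v >= 0 here)
  volume$voxels <- v
  volume
}

#' Extract axial 2-D slices with liver / tumor masks
#'
#' The axial axis is the third array axis; slice indices are 0-based.
#' Per slice, `liver_mask` marks labels in `{1, 2}` (tumor voxels are
#' liver tissue) and `tumor_mask` marks label 2.  With
#' `keep_empty = FALSE` slices without liver pixels are dropped and the
#' kept/dropped counts reported via `message()`.
#'
#' @param volume A [ct_volume()] with labels.
#' @param keep_empty Logical, keep slices with an empty liver mask.
#' @return A list of `slice_pair` objects with fields `image`,
#'   `liver_mask`, `tumor_mask`, `volume_id`, `slice_index`.
#' @export
volume_to_slices <- function(volume, keep_empty = FALSE) {
  stopifnot(inherits(volume, "ct_volume"))
  if (is.null(volume$labels))
    stop("volume has no labels; masks cannot be extracted", call. = FALSE)
  nz <- dim(volume$voxels)[3L]
  out <- vector("list", nz)
  kept <- 0L
  for (z in seq_len(nz)) {
    lab <- volume$labels[, , z]
    liver <- (lab == 1L | lab == 2L) * 1L
    if (!keep_empty && sum(liver) == 0L) next
    kept <- kept + 1L
    out[[if (keep_empty) z else kept]] <- structure(
      list(image = volume$voxels[, , z],
           liver_mask = liver,
           tumor_mask = (lab == 2L) * 1L,
           volume_id = volume$id,
           slice_index = z - 1L),
      class = "slice_pair")
  }
  if (!keep_empty) {
    out <- out[seq_len(kept)]
    message("volume_to_slices: kept ", kept, " of ", nz,
            " slices (", nz - kept, " liver-empty slices dropped)")
  }
  out
}

#' Scale a [0, 255] slice image to a model's input range
#'
#' Self-ONN models take inputs in `[-1, 1]` (powers of magnitudes above 1
#' explode in the MacLaurin series); plain convolution models take
#' `[0, 1]`.
#'
#' @param image Matrix with values in `[0, 255]`.
#' @param style `"selfonn"` (to `[-1, 1]`) or `"conv"` (to `[0, 1]`).
#' @return Scaled matrix.
#' @export
scale_for_model <- function(image, style = c("selfonn", "conv")) {
  style <- match.arg(style)
  if (style == "selfonn") image / 127.5 - 1 else image / 255
}
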