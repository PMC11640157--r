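# Synthetic CT phantoms with LiTS-like structure.
#
# Each phantom volume carries one smooth liver-like elliptical region
# over a consecutive run of axial slices, zero or more hypodense
# disk-shaped tumors strictly inside the liver, Gaussian HU noise on the
# image, and a noiseless {0,1,2} label volume.  The phantoms are
# deliberately easy (high contrast, smooth shapes): they validate the
# segmentation machinery, not clinical difficulty.

#' Phantom generator configuration
#'
#' @param seed Integer master seed; volume `i` is generated from a seed
#'   derived deterministically from `(seed, i)`.
#' @param n_volumes Number of volumes in a generated dataset.
#' @param slices_per_volume Axial slices per volume.
#' @param image_size In-plane size in pixels, divisible by 32, >= 64.
#' @param liver_hu_range Liver tissue HU range (default 50-70).
#' @param tumor_hu_range Tumor HU range (default 10-40); must lie
#'   entirely below the liver range so hypodense contrast exists.
#' @param background_hu Background HU (default -80).
#' @param n_tumors_range Integer range of tumors per volume (default 0-3).
#' @param tumor_radius_range Tumor radius range in pixels.
#' @param noise_sd Gaussian HU noise standard deviation (default 8).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(seed = 1L, n_volumes = 4L,
                           slices_per_volume = 16L, image_size = 64L,
                           liver_hu_range = c(50, 70),
                           tumor_hu_range = c(10, 40),
                           background_hu = -80,
                           n_tumors_range = c(0L, 3L),
                           tumor_radius_range = c(2.5, 6),
                           noise_sd = 8) {
  stopifnot(n_volumes >= 1, slices_per_volume >= 1,
            image_size %% 32 == 0, image_size >= 64,
            noise_sd > 0, tumor_radius_range[1] > 0)
  if (max(tumor_hu_range) >= min(liver_hu_range))
    stop("tumor HU range must lie strictly below the liver HU range",
         call. = FALSE)
  structure(list(seed = as.integer(seed), n_volumes = as.integer(n_volumes),
                 slices_per_volume = as.integer(slices_per_volume),
                 image_size = as.integer(image_size),
                 liver_hu_range = liver_hu_range,
                 tumor_hu_range = tumor_hu_range,
                 background_hu = background_hu,
                 n_tumors_range = as.integer(n_tumors_range),
                 tumor_radius_range = tumor_radius_range,
                 noise_sd = noise_sd),
            class = "phantom_config")
}

#' Generate one phantom volume
#'
#' The liver is a smoothed random ellipse whose centre and axes vary
#' smoothly across a consecutive run of slices; tumors are random
#' constant-radius disks spanning one to three consecutive slices,
#' placed fully inside the liver with hypodense HU.  Noise applies to the
#' HU image only; labels are noiseless.  Output is fully determined by
#' `(config$seed, volume_index)`.
#'
#' @param config A [phantom_config()].
#' @param volume_index 1-based volume index.
#' @return A [ct_volume()] with labels and id `volume-<index>`.
#' @export
generate_phantom_volume <- function(config, volume_index = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed((config$seed * 7919L + volume_index * 104729L) %% 2147483629L)
  n <- config$image_size
  nz <- config$slices_per_volume
  vox <- array(config$background_hu, dim = c(n, n, nz))
  lab <- array(0L, dim = c(n, n, nz))

  # consecutive slice run holding the liver
  run_len <- max(3L, round(nz * stats::runif(1, 0.5, 0.9)))
  run_len <- min(run_len, nz)
  z0 <- sample.int(nz - run_len + 1L, 1L)
  zs <- z0:(z0 + run_len - 1L)

  # smooth per-slice ellipse parameters
  cx0 <- n * stats::runif(1, 0.4, 0.6)
  cy0 <- n * stats::runif(1, 0.4, 0.6)
  rx0 <- n * stats::runif(1, 0.26, 0.34)
  ry0 <- n * stats::runif(1, 0.20, 0.30)
  th0 <- stats::runif(1, 0, pi)
  ph <- stats::runif(4, 0, 2 * pi)
  liver_hu <- stats::runif(1, config$liver_hu_range[1],
                           config$liver_hu_range[2])
  gx <- matrix(rep(seq_len(n), n), nrow = n)
  gy <- t(gx)
  t_rel <- (zs - zs[1]) / max(1L, run_len - 1L)
  shrink <- sqrt(pmax(0.15, 1 - (2 * t_rel - 1)^2))   # taper at run ends
  for (k in seq_along(zs)) {
    z <- zs[k]
    cx <- cx0 + 0.05 * n * sin(2 * pi * t_rel[k] + ph[1])
    cy <- cy0 + 0.05 * n * sin(2 * pi * t_rel[k] + ph[2])
    rx <- rx0 * shrink[k] * (1 + 0.08 * sin(2 * pi * t_rel[k] + ph[3]))
    ry <- ry0 * shrink[k] * (1 + 0.08 * sin(2 * pi * t_rel[k] + ph[4]))
    th <- th0
    xr <- (gx - cx) * cos(th) + (gy - cy) * sin(th)
    yr <- -(gx - cx) * sin(th) + (gy - cy) * cos(th)
    inside <- (xr / rx)^2 + (yr / ry)^2 <= 1
    vox[, , z][inside] <- liver_hu
    lab[, , z][inside] <- 1L
  }

  # tumors: short disk stacks fully inside the liver
  n_tum <- if (config$n_tumors_range[2] > config$n_tumors_range[1])
    sample(config$n_tumors_range[1]:config$n_tumors_range[2], 1L)
  else config$n_tumors_range[1]
  placed <- 0L
  attempts <- 0L
  zaspect <- 2.5          # slice thickness relative to in-plane pixel size
  while (placed < n_tum && attempts < 200L) {
    attempts <- attempts + 1L
    r <- stats::runif(1, config$tumor_radius_range[1],
                      config$tumor_radius_range[2])
    # a tumor appears as a constant-radius disk on a short run of
    # consecutive slices (in-plane radius r px, extent about 2r mm
    # across slices of 2.5 mm)
    next_t <- max(1L, min(3L, round(2 * r / zaspect)))
    zc <- sample(zs, 1L)
    zr <- zc:min(max(zs), zc + next_t - 1L)
    sl <- lab[, , zc]
    if (sum(sl == 1L) < 4 * r^2) next    # slice too small for this tumor
    liver_px <- which(sl == 1L, arr.ind = TRUE)
    ctr <- liver_px[sample.int(nrow(liver_px), 1L), ]
    disk <- (gx - ctr[1])^2 + (gy - ctr[2])^2 <= r^2
    ok <- TRUE
    vox_sel <- list()
    for (z in zr) {
      if (any(disk & lab[, , z] == 0L)) { ok <- FALSE; break }
      vox_sel[[length(vox_sel) + 1L]] <- list(z = z, disk = disk)
    }
    if (!ok || !length(vox_sel)) next
    tum_hu <- stats::runif(1, config$tumor_hu_range[1],
                           config$tumor_hu_range[2])
    for (s in vox_sel) {
      vox[, , s$z][s$disk] <- tum_hu
      lab[, , s$z][s$disk] <- 2L
    }
    placed <- placed + 1L
  }
  if (placed < n_tum && n_tum > 0L && placed == 0L && attempts >= 200L)
    stop("could not place any tumor inside the liver after 200 attempts; ",
         "tumor_radius_range is too large for the liver size",
         call. = FALSE)

  vox <- vox + array(stats::rnorm(length(vox), 0, config$noise_sd),
                     dim = dim(vox))
  ct_volume(vox, spacing = c(1, 1, 2.5), affine = diag(4), labels = lab,
            id = paste0("volume-", volume_index))
}

#' Generate a LiTS-style phantom dataset on disk
#'
#' Writes `volume-i.nii.gz` / `segmentation-i.nii.gz` pairs plus a
#' `manifest.csv` with one row per volume.
#'
#' @param config A [phantom_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest as a data frame (columns `volume_id`,
#'   `volume_path`, `segmentation_path`, `n_slices`, `n_liver_px`,
#'   `n_tumor_px`), invisibly written to `manifest.csv`.
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "phantom_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", config$n_volumes)
  for (i in seq_len(config$n_volumes)) {
    vol <- generate_phantom_volume(config, i)
    vp <- file.path(out_dir, paste0("volume-", i, ".nii.gz"))
    sp <- file.path(out_dir, paste0("segmentation-", i, ".nii.gz"))
    write_nifti_volume(vol, vp, sp)
    rows[[i]] <- data.frame(volume_id = vol$id, volume_path = vp,
                            segmentation_path = sp,
                            n_slices = dim(vol$voxels)[3L],
                            n_liver_px = sum(vol$labels >= 1L),
                            n_tumor_px = sum(vol$labels == 2L))
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
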