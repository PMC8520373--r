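#' CT volume container
#'
#' A 3-D array of Hounsfield units with voxel spacing. The third array axis
#' indexes axial slices.
#'
#' @param voxels 3-D numeric array of HU values (finite; CT scanners report
#'   roughly -1024..3071).
#' @param spacing_mm Positive numeric triple: voxel spacing (x, y, z) in mm.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing_mm = c(1, 1, 1)) {
  if (length(dim(voxels)) != 3L) stopf("`voxels` must be a 3-D array")
  if (!all(is.finite(voxels))) stopf("HU values must be finite")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stopf("`spacing_mm` must be three positive numbers")
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %g x %g x %g mm, HU [%g, %g]\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2],
              x$spacing_mm[3], min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Fat attenuation window
#'
#' The Hounsfield-unit window that selects adipose tissue. The default
#' (-150, -50) HU is the standard CT fat window used for epicardial fat
#' quantification.
#'
#' @param hu_low,hu_high Window bounds in HU, `hu_low < hu_high`.
#' @return An object of class `fat_window`.
#' @export
fat_window <- function(hu_low = -150, hu_high = -50) {
  check_scalar_num(hu_low, "hu_low"); check_scalar_num(hu_high, "hu_high")
  if (hu_low >= hu_high) stopf("`hu_low` must be below `hu_high`")
  structure(list(hu_low = hu_low, hu_high = hu_high), class = "fat_window")
}

#' Axial slice bounds
#'
#' Inclusive first and last axial slice of the measurement range. Clinically
#' these delimit the span from the origin of the left pulmonary artery to
#' the apex of the left ventricle, picked manually on the workstation; the
#' package takes the resulting explicit slice indices.
#'
#' @param start_slice,end_slice 1-based inclusive slice indices,
#'   `start_slice <= end_slice`.
#' @return An object of class `slice_bounds`.
#' @export
slice_bounds <- function(start_slice, end_slice) {
  if (start_slice < 1 || end_slice < start_slice ||
      start_slice != round(start_slice) || end_slice != round(end_slice))
    stopf("need 1 <= start_slice <= end_slice (integers)")
  structure(list(start_slice = as.integer(start_slice),
                 end_slice = as.integer(end_slice)), class = "slice_bounds")
}

#' Segment fat voxels by HU window within slice bounds
#'
#' @param volume A [ct_volume()].
#' @param window A [fat_window()].
#' @param bounds A [slice_bounds()]; must lie within the volume. Default:
#'   all slices.
#' @return Logical 3-D array, `TRUE` exactly where
#'   `hu_low <= HU <= hu_high` and the slice index is within bounds.
#' @export
segment_fat <- function(volume, window = fat_window(), bounds = NULL) {
  stopifnot(inherits(volume, "ct_volume"), inherits(window, "fat_window"))
  n_slices <- dim(volume$voxels)[3]
  if (is.null(bounds)) bounds <- slice_bounds(1, n_slices)
  stopifnot(inherits(bounds, "slice_bounds"))
  if (bounds$end_slice > n_slices)
    stopf("slice bounds [%d, %d] exceed the %d slices in the volume",
          bounds$start_slice, bounds$end_slice, n_slices)
  mask <- volume$voxels >= window$hu_low & volume$voxels <= window$hu_high
  keep <- seq(bounds$start_slice, bounds$end_slice)
  mask[, , setdiff(seq_len(n_slices), keep)] <- FALSE
  mask
}

#' Measure segmented volume in milliliters
#'
#' Volume = voxel count x voxel volume (mm^3) / 1000.
#'
#' @param mask Logical 3-D array (e.g. from [segment_fat()]).
#' @param spacing_mm Positive voxel spacing triple in mm.
#' @param window,bounds Optional [fat_window()] / [slice_bounds()] recorded
#'   in the result for provenance.
#' @return An object of class `eat_measurement`: list with `volume_ml`,
#'   `voxel_count`, `window`, `bounds`.
#' @examples
#' m <- array(FALSE, c(10, 10, 10)); m[1:10, 1:10, 1:10] <- TRUE
#' measure_eat(m, c(1, 1, 1))$volume_ml  # 1 mL
#' @export
measure_eat <- function(mask, spacing_mm, window = NULL, bounds = NULL) {
  if (!is.logical(mask)) stopf("`mask` must be a logical array")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stopf("`spacing_mm` must be three positive numbers")
  count <- sum(mask)
  structure(list(volume_ml = count * prod(spacing_mm) / 1000,
                 voxel_count = count, window = window, bounds = bounds),
            class = "eat_measurement")
}

#' @export
print.eat_measurement <- function(x, ...) {
  cat(sprintf("<eat_measurement> %.2f mL (%d voxels)\n",
              x$volume_ml, x$voxel_count))
  invisible(x)
}

#' Average two readers' measurements
#'
#' Mirrors the clinical protocol in which two readers measure independently
#' and the results are averaged.
#'
#' @param a,b `eat_measurement` objects.
#' @return An `eat_measurement` with averaged volume and voxel count.
#' @export
average_eat <- function(a, b) {
  stopifnot(inherits(a, "eat_measurement"), inherits(b, "eat_measurement"))
  structure(list(volume_ml = (a$volume_ml + b$volume_ml) / 2,
                 voxel_count = (a$voxel_count + b$voxel_count) / 2,
                 window = a$window, bounds = a$bounds),
            class = "eat_measurement")
}

#' Synthetic torso-like CT volume with a known fat shell
#'
#' Builds a test volume: air background (-1000 HU), a soft-tissue ellipsoid
#' (+40 HU) and an embedded adipose shell (-100 HU) whose voxel count is
#' returned as ground truth, plus optional Gaussian HU noise. The shell
#' stands in for a delineated pericardial sac: it occupies the outer layer
#' of the ellipsoid, with thickness set so the shell holds `fat_fraction`
#' of the ellipsoid volume.
#'
#' @param n_slices Number of axial slices.
#' @param slice_shape Integer pair: in-plane dimensions.
#' @param fat_fraction Fraction of the ellipsoid volume occupied by the fat
#'   shell, in (0, 1).
#' @param noise_sd_hu Standard deviation of additive Gaussian HU noise
#'   (0 = noiseless).
#' @param seed Integer seed; the volume is deterministic given the seed.
#' @param spacing_mm Voxel spacing triple.
#' @return List with `volume` (a [ct_volume()]) and `true_fat_voxels`
#'   (integer count of shell voxels before noise).
#' @export
generate_synthetic_ct <- function(n_slices, slice_shape = c(64, 64),
                                  fat_fraction = 0.3, noise_sd_hu = 0,
                                  seed = 1, spacing_mm = c(1, 1, 1)) {
  if (fat_fraction <= 0 || fat_fraction >= 1)
    stopf("`fat_fraction` must lie strictly between 0 and 1")
  if (noise_sd_hu < 0) stopf("`noise_sd_hu` must be non-negative")
  nx <- slice_shape[1]; ny <- slice_shape[2]; nz <- n_slices
  # normalized coordinates in [-1, 1] per axis
  cx <- (2 * seq_len(nx) - nx - 1) / nx
  cy <- (2 * seq_len(ny) - ny - 1) / ny
  cz <- (2 * seq_len(nz) - nz - 1) / nz
  R2 <- outer(outer((cx / 0.8)^2, (cy / 0.8)^2, `+`), (cz / 0.9)^2, `+`)
  inner_scale <- (1 - fat_fraction)^(1 / 3)
  outer_mask <- R2 <= 1
  inner_mask <- R2 <= inner_scale^2
  shell <- outer_mask & !inner_mask
  vox <- array(-1000, dim = c(nx, ny, nz))
  vox[inner_mask] <- 40
  vox[shell] <- -100
  if (noise_sd_hu > 0) {
    vox <- with_seed(seed, vox + array(rnorm(length(vox), 0, noise_sd_hu),
                                       dim = dim(vox)))
    vox <- pmin(pmax(vox, -1024), 3071)
  }
  list(volume = ct_volume(vox, spacing_mm), true_fat_voxels = sum(shell))
}

#' Read / write CT volumes as NIfTI
#'
#' Thin wrappers over RNifti preserving voxel spacing.
#'
#' @param path `.nii` or `.nii.gz` file path.
#' @param volume A [ct_volume()].
#' @return `read_ct_nifti` returns a [ct_volume()].
#' @export
read_ct_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  ct_volume(array(as.numeric(img), dim = dim(img)),
            spacing_mm = RNifti::pixdim(img)[1:3])
}

#' @rdname read_ct_nifti
#' @export
write_ct_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
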