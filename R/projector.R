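#' Build the sparse system matrix
#'
#' Traces one ray per detector bin and projection angle through the pixel
#' grid (Siddon's algorithm, compiled) and assembles the sparse matrix of
#' ray-pixel intersection lengths \eqn{q_{ij}} — the forward model shared by
#' MLEM and OSEM. Rays are indexed angle-major: ray \eqn{i = (a-1) n_d + d}
#' for angle index \eqn{a} and detector bin \eqn{d}; pixels use the
#' column-major index of the image matrix.
#'
#' @param geometry A [make_geometry()] projection geometry. The detector
#'   array must cover the image diagonal.
#' @param grid An [image_grid()] (only its dimensions and pixel size are
#'   used).
#' @param cache_path Optional path; if given and the file exists the matrix
#'   is read from it, otherwise the built matrix is saved there
#'   (`saveRDS`). Ray tracing at benchmark scale is the dominant setup cost.
#' @return An object of class `system_matrix`: list with `A` (a
#'   `Matrix::dgCMatrix`, rays x pixels), `geometry`, `n_row`, `n_col`,
#'   `pixel_size`, and `ray_angle` (angle index of each ray).
#' @export
build_system_matrix <- function(geometry, grid, cache_path = NULL) {
  stopifnot(inherits(geometry, "projection_geometry"))
  n_row <- nrow(grid); n_col <- ncol(grid)
  px <- pixel_size_of(grid)
  diag_len <- px * sqrt(n_row^2 + n_col^2)
  if (geometry$n_detectors * geometry$detector_spacing < diag_len)
    stopf("detector array (%g) narrower than the image diagonal (%g): incomplete coverage",
          geometry$n_detectors * geometry$detector_spacing, diag_len)
  if (!is.null(cache_path) && file.exists(cache_path)) {
    sm <- readRDS(cache_path)
    if (identical(dim(sm$A), c(length(geometry$angles_deg) * geometry$n_detectors,
                               n_row * n_col)))
      return(sm)
  }
  tr <- .siddon_trace(geometry$angles_deg, geometry$n_detectors,
                      geometry$detector_spacing * px, n_row, n_col, px)
  n_rays <- length(geometry$angles_deg) * geometry$n_detectors
  A <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(n_rays, n_row * n_col))
  sm <- structure(list(
    A = A, geometry = geometry, n_row = n_row, n_col = n_col,
    pixel_size = px,
    ray_angle = rep(seq_along(geometry$angles_deg),
                    each = geometry$n_detectors)
  ), class = "system_matrix")
  if (!is.null(cache_path)) saveRDS(sm, cache_path)
  sm
}

#' @export
print.system_matrix <- function(x, ...) {
  cat(sprintf("<system_matrix> %d rays x %d pixels, %d nonzeros (%d angles, %d detectors)\n",
              nrow(x$A), ncol(x$A), length(x$A@x),
              length(x$geometry$angles_deg), x$geometry$n_detectors))
  invisible(x)
}

#' Sinogram container
#'
#' Line-integral projections arranged as one row per projection angle and
#' one column per detector bin.
#'
#' @param values Numeric matrix, `n_angles` x `n_detectors`.
#' @param geometry The [make_geometry()] the projections were taken under.
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(values, geometry) {
  stopifnot(inherits(geometry, "projection_geometry"))
  values <- as.matrix(values)
  if (nrow(values) != length(geometry$angles_deg) ||
      ncol(values) != geometry$n_detectors)
    stopf("sinogram must be n_angles (%d) x n_detectors (%d)",
          length(geometry$angles_deg), geometry$n_detectors)
  if (!all(is.finite(values))) stopf("sinogram values must be finite")
  structure(list(values = values, geometry = geometry), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d angles x %d detectors, range [%g, %g]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

# Flatten a sinogram to the angle-major ray vector the system matrix uses.
ray_vector <- function(sino) as.vector(t(sino$values))

ray_matrix <- function(v, geometry) {
  sinogram(matrix(v, nrow = length(geometry$angles_deg),
                  ncol = geometry$n_detectors, byrow = TRUE), geometry)
}

#' Forward projection
#'
#' Computes \eqn{y_i = \sum_j q_{ij} g_j} for every ray, i.e. the noiseless
#' sinogram of an image under the system matrix.
#'
#' @param sm A [build_system_matrix()] object.
#' @param image An [image_grid()] with matching dimensions; must be
#'   non-negative.
#' @return A [sinogram()].
#' @export
forward_project <- function(sm, image) {
  stopifnot(inherits(sm, "system_matrix"))
  if (nrow(image) != sm$n_row || ncol(image) != sm$n_col)
    stopf("image is %d x %d but the system matrix expects %d x %d",
          nrow(image), ncol(image), sm$n_row, sm$n_col)
  if (min(image) < 0) stopf("image must be non-negative")
  y <- as.numeric(sm$A %*% as.vector(image))
  ray_matrix(y, sm$geometry)
}

#' Forward projection restricted to a subset of angles
#'
#' The OSEM sub-iteration projector: projections only for rays whose angle
#' index lies in `subset`. Concatenating the outputs over a partition of the
#' angles reorders to the full [forward_project()] sinogram.
#'
#' @param sm A [build_system_matrix()] object.
#' @param image An [image_grid()].
#' @param subset Integer vector of angle indices (1-based). May be empty.
#' @return Numeric vector of projections for the subset's rays, ordered
#'   angle-major (in the order the angles appear in `subset`).
#' @export
forward_project_subset <- function(sm, image, subset) {
  stopifnot(inherits(sm, "system_matrix"))
  subset <- as.integer(subset)
  if (length(subset) == 0L) return(numeric(0))
  n_ang <- length(sm$geometry$angles_deg)
  if (any(subset < 1L | subset > n_ang))
    stopf("subset angle indices must lie in 1..%d", n_ang)
  rows <- subset_ray_rows(sm, subset)
  as.numeric(sm$A[rows, , drop = FALSE] %*% as.vector(image))
}

# Ray row indices belonging to the given angle indices, angle-major.
subset_ray_rows <- function(sm, subset) {
  nd <- sm$geometry$n_detectors
  as.vector(vapply(as.integer(subset),
                   function(a) (a - 1L) * nd + seq_len(nd),
                   integer(nd)))
}

#' Read / write sinograms as CSV
#'
#' One row per projection angle, one column per detector bin; the header row
#' carries detector indices `d1..dK` and the first column the angle in
#' degrees.
#'
#' @param sino A [sinogram()].
#' @param path CSV file path.
#' @param geometry Geometry to attach when reading.
#' @return `read_sinogram_csv` returns a [sinogram()].
#' @export
write_sinogram_csv <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  df <- data.frame(angle_deg = sino$geometry$angles_deg, sino$values)
  names(df) <- c("angle_deg", paste0("d", seq_len(ncol(sino$values))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sinogram_csv
#' @export
read_sinogram_csv <- function(path, geometry) {
  df <- utils::read.csv(path, check.names = FALSE)
  sinogram(as.matrix(df[, -1, drop = FALSE]), geometry)
}
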