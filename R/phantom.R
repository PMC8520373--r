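#' Image grid container
#'
#' A square (or rectangular) pixel grid holding one intensity per pixel,
#' the image object that the projector and the reconstruction iterate on.
#'
#' @param values Numeric matrix of pixel intensities (rows = image rows).
#' @param pixel_size Physical side length of one pixel (arbitrary units,
#'   default 1.0). Detector spacing and intersection lengths are measured in
#'   the same unit.
#' @return An object of class `image_grid`: the matrix with a `pixel_size`
#'   attribute.
#' @export
image_grid <- function(values, pixel_size = 1.0) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stopf("image intensities must all be finite")
  check_scalar_num(pixel_size, "pixel_size")
  if (pixel_size <= 0) stopf("`pixel_size` must be positive")
  structure(values, pixel_size = pixel_size, class = c("image_grid", "matrix"))
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d pixels, pixel_size = %g, range [%g, %g]\n",
              nrow(x), ncol(x), attr(x, "pixel_size"), min(x), max(x)))
  invisible(x)
}

pixel_size_of <- function(grid) {
  ps <- attr(grid, "pixel_size")
  if (is.null(ps)) 1.0 else ps
}

# Shepp-Logan ellipse table (original low-contrast amplitudes; rim 1.0).
# Columns: additive intensity, semi-axis x, semi-axis y, center x, center y,
# rotation (degrees, counter-clockwise). Coordinates are normalized to the
# [-1, 1] square.
shepp_logan_ellipses <- function() {
  m <- matrix(c(
     1.00, 0.6900, 0.9200,  0.00,  0.0000,   0,
    -0.98, 0.6624, 0.8740,  0.00, -0.0184,   0,
    -0.02, 0.1100, 0.3100,  0.22,  0.0000, -18,
    -0.02, 0.1600, 0.4100, -0.22,  0.0000,  18,
     0.01, 0.2100, 0.2500,  0.00,  0.3500,   0,
     0.01, 0.0460, 0.0460,  0.00,  0.1000,   0,
     0.01, 0.0460, 0.0460,  0.00, -0.1000,   0,
     0.01, 0.0460, 0.0230, -0.08, -0.6050,   0,
     0.01, 0.0230, 0.0230,  0.00, -0.6060,   0,
     0.01, 0.0230, 0.0460,  0.06, -0.6050,   0
  ), ncol = 6, byrow = TRUE)
  colnames(m) <- c("intensity", "a", "b", "x0", "y0", "phi_deg")
  m
}

rasterize_ellipses <- function(n, ellipses) {
  # pixel centers on the normalized [-1, 1] square, row 1 = top
  xs <- (2 * seq_len(n) - n - 1) / n
  ys <- rev(xs)
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(ys, n, n)
  img <- matrix(0, n, n)
  for (k in seq_len(nrow(ellipses))) {
    e <- ellipses[k, ]
    phi <- e[["phi_deg"]] * pi / 180
    dx <- X - e[["x0"]]; dy <- Y - e[["y0"]]
    u <- ( dx * cos(phi) + dy * sin(phi)) / e[["a"]]
    v <- (-dx * sin(phi) + dy * cos(phi)) / e[["b"]]
    img <- img + e[["intensity"]] * (u * u + v * v <= 1)
  }
  img
}

#' Generate the Shepp-Logan head phantom
#'
#' Rasterizes the standard ten-ellipse Shepp-Logan phantom (original
#' low-contrast amplitudes, values in \[0, 1\]) on an `n` x `n` grid by
#' evaluating the ellipse table at pixel centers. Used as the ground-truth
#' image for the reconstruction experiments.
#'
#' @param n Side length in pixels (>= 16); the benchmark experiment uses 256.
#' @param pixel_size Physical pixel size (default 1.0).
#' @return An [image_grid()] with intensities clipped to be non-negative.
#' @examples
#' ph <- generate_shepp_logan(64)
#' range(ph)
#' @export
generate_shepp_logan <- function(n, pixel_size = 1.0) {
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 16)
    stopf("`n` must be a single integer >= 16")
  img <- rasterize_ellipses(as.integer(n), shepp_logan_ellipses())
  img[img < 0] <- 0
  image_grid(img, pixel_size = pixel_size)
}
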