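#' Parallel-beam projection geometry
#'
#' Defines the set of equally spaced projection angles and the linear detector
#' array used by the projector. Angle 0 corresponds to rays parallel to the
#' y-axis; angles increase counter-clockwise and live in \[0, `span_deg`).
#'
#' @param interval_deg Angular spacing between successive projections, in
#'   degrees (the benchmark uses 1).
#' @param span_deg Total angular span in degrees; must be an integer multiple
#'   of `interval_deg`. Parallel-beam data are redundant beyond 180, the
#'   default.
#' @param n_detectors Number of detector bins; must cover the image diagonal.
#'   See [default_detector_count()].
#' @param detector_spacing Center-to-center detector spacing in pixel units
#'   (default 1.0 = one pixel).
#' @return An object of class `projection_geometry` with fields `angles_deg`,
#'   `angular_interval_deg`, `n_detectors`, `detector_spacing`.
#' @examples
#' make_geometry(30, 180, 95)$angles_deg
#' @export
make_geometry <- function(interval_deg, span_deg = 180, n_detectors,
                          detector_spacing = 1.0) {
  check_scalar_num(interval_deg, "interval_deg")
  check_scalar_num(span_deg, "span_deg")
  if (interval_deg <= 0) stopf("`interval_deg` must be positive")
  if (span_deg <= 0 || span_deg > 180)
    stopf("`span_deg` must lie in (0, 180]: parallel-beam projections repeat beyond 180 degrees")
  n_ang <- span_deg / interval_deg
  if (abs(n_ang - round(n_ang)) > 1e-9)
    stopf("`span_deg` (%g) is not an integer multiple of `interval_deg` (%g)",
          span_deg, interval_deg)
  n_ang <- as.integer(round(n_ang))
  if (!is.numeric(n_detectors) || n_detectors < 1 ||
      n_detectors != round(n_detectors))
    stopf("`n_detectors` must be a positive integer")
  if (detector_spacing <= 0) stopf("`detector_spacing` must be positive")
  structure(list(
    angles_deg = interval_deg * (seq_len(n_ang) - 1L),
    angular_interval_deg = interval_deg,
    span_deg = span_deg,
    n_detectors = as.integer(n_detectors),
    detector_spacing = detector_spacing
  ), class = "projection_geometry")
}

#' @export
print.projection_geometry <- function(x, ...) {
  cat(sprintf("<projection_geometry> %d angles at %g deg over [0, %g), %d detectors (spacing %g)\n",
              length(x$angles_deg), x$angular_interval_deg, x$span_deg,
              x$n_detectors, x$detector_spacing))
  invisible(x)
}

#' Default detector count for an n x n image
#'
#' Smallest odd number of unit-spaced detector bins covering the image
#' diagonal `n * sqrt(2)` with a two-bin margin on each side, so every pixel
#' is seen at every angle (367 for n = 256).
#'
#' @param n Image side length in pixels.
#' @return Odd integer detector count.
#' @export
default_detector_count <- function(n) {
  d <- ceiling(n * sqrt(2) + 4)
  as.integer(if (d %% 2 == 0) d + 1 else d)
}

#' Serialize / read projection geometry as JSON
#'
#' @param geometry A [make_geometry()] object.
#' @param path Output (or input) JSON file path.
#' @return `read_geometry_json` returns a `projection_geometry`.
#' @export
write_geometry_json <- function(geometry, path) {
  stopifnot(inherits(geometry, "projection_geometry"))
  jsonlite::write_json(list(
    interval_deg = geometry$angular_interval_deg,
    span_deg = geometry$span_deg,
    n_detectors = geometry$n_detectors,
    detector_spacing = geometry$detector_spacing
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  make_geometry(g$interval_deg, g$span_deg, g$n_detectors, g$detector_spacing)
}
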