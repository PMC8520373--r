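#' Reconstruction configuration
#'
#' @param n_iterations Number of full iterations (each full OSEM iteration
#'   sweeps every subset once).
#' @param epsilon Division guard used in the residual and sensitivity
#'   denominators; must lie in (0, 1e-6]. Default 1e-12.
#' @param seed Optional integer recorded for provenance; the deterministic
#'   EM core does not consume randomness.
#' @param track_loglik If `TRUE` (default) the Poisson log-likelihood is
#'   recorded after every full iteration (one extra forward projection each).
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(n_iterations, epsilon = 1e-12, seed = NULL,
                         track_loglik = TRUE) {
  if (!is.numeric(n_iterations) || n_iterations < 1 ||
      n_iterations != round(n_iterations))
    stopf("`n_iterations` must be a positive integer")
  check_scalar_num(epsilon, "epsilon")
  if (epsilon <= 0 || epsilon > 1e-6)
    stopf("`epsilon` must lie in (0, 1e-6]")
  structure(list(n_iterations = as.integer(n_iterations), epsilon = epsilon,
                 seed = seed, track_loglik = isTRUE(track_loglik)),
            class = "recon_config")
}

#' Uniform positive initial image
#'
#' EM updates are multiplicative, so any strictly positive constant start
#' works; all-ones makes the first correction factor directly interpretable.
#'
#' @param grid An [image_grid()] giving the dimensions and pixel size.
#' @return An [image_grid()] of ones.
#' @export
init_image <- function(grid) {
  image_grid(matrix(1, nrow(grid), ncol(grid)),
             pixel_size = pixel_size_of(grid))
}

#' Partition projection angles into ordered subsets
#'
#' Splits `n_angles` angle indices into `L = n_angles / per_subset` disjoint
#' subsets by a stride-L interleave, so each subset's angles are uniformly
#' spread over the angular span (balanced, symmetric subsets). The
#' processing order is either the natural one (`sequential`) or the
#' angular-distance-optimized one (`optimized`): a greedy sweep that makes
#' each subset's lead angle as far as possible, in the circular metric of
#' the subset pattern period, from the subset processed just before it
#' (ties broken by lowest subset index). Processing well-separated subsets
#' consecutively feeds each sub-iteration the least redundant directions and
#' speeds early convergence.
#'
#' @param n_angles Total number of projection angles.
#' @param per_subset Projection directions per subset; must divide
#'   `n_angles`. The benchmark uses 6 (with 180 angles, L = 30).
#' @param strategy `"sequential"` or `"optimized"`.
#' @return An object of class `subset_partition`: list with `L`, `subsets`
#'   (list of 1-based angle-index vectors S_1..S_L), `order` (processing
#'   permutation of 1..L), `strategy`.
#' @examples
#' partition_subsets(8, 2, "optimized")$order  # 1 3 2 4
#' @export
partition_subsets <- function(n_angles,
                              per_subset,
                              strategy = c("sequential", "optimized")) {
  strategy <- match.arg(strategy)
  if (n_angles < 1 || n_angles != round(n_angles))
    stopf("`n_angles` must be a positive integer")
  if (per_subset < 1 || per_subset != round(per_subset) ||
      n_angles %% per_subset != 0)
    stopf("`per_subset` (%s) must be a positive divisor of `n_angles` (%s)",
          per_subset, n_angles)
  n_angles <- as.integer(n_angles); per_subset <- as.integer(per_subset)
  L <- n_angles %/% per_subset
  subsets <- lapply(seq_len(L), function(m) seq(m, n_angles, by = L))
  ord <- if (strategy == "sequential" || L == 1L) seq_len(L) else {
    # circular distance between lead offsets on the period-L index circle
    cdist <- function(a, b) { d <- abs(a - b) %% L; pmin(d, L - d) }
    ord <- integer(L); ord[1L] <- 1L
    remaining <- setdiff(seq_len(L), 1L)
    for (k in seq_len(L - 1L)) {
      d <- cdist(remaining - 1L, ord[k] - 1L)
      pick <- remaining[which.max(d)]  # which.max takes the first = lowest index
      ord[k + 1L] <- pick
      remaining <- setdiff(remaining, pick)
    }
    ord
  }
  structure(list(L = L, subsets = subsets, order = ord, strategy = strategy),
            class = "subset_partition")
}

#' @export
print.subset_partition <- function(x, ...) {
  cat(sprintf("<subset_partition> L = %d subsets of %d angles, %s ordering\n",
              x$L, length(x$subsets[[1L]]), x$strategy))
  invisible(x)
}

#' Residual of observed against theoretical projections
#'
#' The multiplicative EM residual \eqn{r_i = y_i / \max(\hat y_i, \epsilon)}:
#' the ratio of the actual projection to the theoretical projection of the
#' current image estimate.
#'
#' @param observed Non-negative numeric vector of measured projections.
#' @param theoretical Numeric vector of the same length (current forward
#'   projection).
#' @param epsilon Division guard (so a zero theoretical projection with zero
#'   observation yields residual 0, not NaN).
#' @return Numeric residual vector.
#' @export
compute_residual <- function(observed, theoretical, epsilon = 1e-12) {
  if (length(observed) != length(theoretical))
    stopf("observed and theoretical projections differ in length")
  if (any(observed < 0)) stopf("observed projections must be non-negative")
  observed / pmax(theoretical, epsilon)
}

#' Back-projected correction factor for one subset
#'
#' \eqn{c_j = \sum_{i \in S_m} q_{ij} r_i / \sum_{i \in S_m} q_{ij}}; pixels
#' with zero sensitivity under the subset (no ray touches them) receive
#' correction 1 and are left unchanged.
#'
#' @param sm A [build_system_matrix()] object.
#' @param residual Residual vector for the subset's rays (angle-major order,
#'   as produced by [compute_residual()] on [forward_project_subset()]
#'   output).
#' @param subset Non-empty integer vector of angle indices.
#' @return An [image_grid()] of correction factors.
#' @export
compute_correction <- function(sm, residual, subset) {
  stopifnot(inherits(sm, "system_matrix"))
  subset <- as.integer(subset)
  if (length(subset) == 0L) stopf("`subset` must contain at least one angle")
  rows <- subset_ray_rows(sm, subset)
  if (length(residual) != length(rows))
    stopf("residual has %d values but the subset has %d rays",
          length(residual), length(rows))
  As <- sm$A[rows, , drop = FALSE]
  sens <- as.numeric(Matrix::colSums(As))
  num <- as.numeric(Matrix::crossprod(As, residual))
  corr <- ifelse(sens > 0, num / pmax(sens, .Machine$double.xmin), 1)
  image_grid(matrix(corr, sm$n_row, sm$n_col), pixel_size = sm$pixel_size)
}

#' Multiplicative EM image update
#'
#' \eqn{g^{new}_j = g^k_j c_j}: applies one subset's correction factors and
#' advances the sub-iteration counter. Positivity is preserved (a zero pixel
#' stays zero).
#'
#' @param state A `recon_state` (see [osem_reconstruct()]).
#' @param correction Correction image from [compute_correction()]; must be
#'   non-negative.
#' @return The updated `recon_state`.
#' @export
apply_update <- function(state, correction) {
  stopifnot(inherits(state, "recon_state"))
  if (!identical(dim(state$image), dim(correction)))
    stopf("correction dimensions do not match the image")
  if (min(correction) < 0) stopf("correction factors must be non-negative")
  state$image <- image_grid(unclass(state$image) * unclass(correction),
                            pixel_size = pixel_size_of(state$image))
  state$sub_iterations_done <- state$sub_iterations_done + 1L
  state
}

new_recon_state <- function(image) {
  structure(list(image = image, k = 0L, sub_iterations_done = 0L,
                 error_history = numeric(0), loglik_history = numeric(0)),
            class = "recon_state")
}

#' @export
print.recon_state <- function(x, ...) {
  cat(sprintf("<recon_state> %d full iterations (%d sub-iterations)",
              x$k, x$sub_iterations_done))
  if (length(x$error_history))
    cat(sprintf(", last error %.4g", x$error_history[length(x$error_history)]))
  cat("\n")
  invisible(x)
}

#' Ordered-subset EM (OSEM) reconstruction
#'
#' Iterative maximum-likelihood reconstruction accelerated by ordered
#' subsets: each full iteration sweeps the subsets in the partition's
#' processing order, and for each subset performs forward projection,
#' residual, back-projected correction and multiplicative image update. With
#' L subsets the image is corrected L times per pass over the data, giving
#' roughly L-fold faster convergence than MLEM at the same cost per pass.
#'
#' @param y A [sinogram()] of non-negative measurements.
#' @param sm The [build_system_matrix()] used to model the projections.
#' @param partition A [partition_subsets()] object over the geometry's
#'   angles.
#' @param config A [recon_config()].
#' @param truth Optional ground-truth [image_grid()]; if given, the relative
#'   RMSE against it is appended to `error_history` after each full
#'   iteration.
#' @param initial Optional starting image (default [init_image()], uniform
#'   ones).
#' @return A `recon_state` with the final `image`, iteration counters, and
#'   `error_history` / `loglik_history` (one entry per full iteration).
#' @export
osem_reconstruct <- function(y, sm, partition, config, truth = NULL,
                             initial = NULL) {
  stopifnot(inherits(y, "sinogram"), inherits(sm, "system_matrix"),
            inherits(partition, "subset_partition"),
            inherits(config, "recon_config"))
  n_ang <- length(sm$geometry$angles_deg)
  if (sum(lengths(partition$subsets)) != n_ang)
    stopf("partition covers %d angles but the geometry has %d",
          sum(lengths(partition$subsets)), n_ang)
  if (min(y$values) < 0) stopf("sinogram must be non-negative")
  yv <- ray_vector(y)

  # precompute each subset's rows, matrix block, transpose and sensitivity
  ord <- partition$order
  blocks <- lapply(ord, function(m) {
    rows <- subset_ray_rows(sm, partition$subsets[[m]])
    As <- sm$A[rows, , drop = FALSE]
    sens <- as.numeric(Matrix::colSums(As))
    list(At = Matrix::t(As), sens = sens, zero = sens == 0,
         y = yv[rows], As = As)
  })

  state <- new_recon_state(if (is.null(initial)) init_image(
    image_grid(matrix(0, sm$n_row, sm$n_col), sm$pixel_size)) else initial)
  if (min(state$image) < 0) stopf("initial image must be non-negative")

  g <- as.vector(state$image)
  eps <- config$epsilon
  for (it in seq_len(config$n_iterations)) {
    for (b in blocks) {
      yhat <- as.numeric(b$As %*% g)
      r <- b$y / pmax(yhat, eps)
      corr <- as.numeric(b$At %*% r) / pmax(b$sens, .Machine$double.xmin)
      corr[b$zero] <- 1
      g <- g * corr
      state$sub_iterations_done <- state$sub_iterations_done + 1L
    }
    state$k <- it
    if (!is.null(truth))
      state$error_history <- c(state$error_history,
                               rel_rmse_vec(g, as.vector(truth)))
    if (config$track_loglik) {
      yhat_full <- as.numeric(sm$A %*% g)
      state$loglik_history <- c(state$loglik_history,
                                sum(yv * log(pmax(yhat_full, eps)) - yhat_full))
    }
  }
  state$image <- image_grid(matrix(g, sm$n_row, sm$n_col),
                            pixel_size = sm$pixel_size)
  state
}

#' Maximum-likelihood EM (MLEM) reconstruction
#'
#' The classical EM reconstruction using all projections in every update:
#' identical to [osem_reconstruct()] with the single-subset partition
#' (L = 1). Monotonically non-decreasing in the Poisson data likelihood.
#'
#' @inheritParams osem_reconstruct
#' @return A `recon_state`.
#' @export
mlem_reconstruct <- function(y, sm, config, truth = NULL, initial = NULL) {
  n_ang <- length(sm$geometry$angles_deg)
  osem_reconstruct(y, sm, partition_subsets(n_ang, n_ang, "sequential"),
                   config, truth = truth, initial = initial)
}

rel_rmse_vec <- function(recon, truth) {
  denom <- sqrt(sum(truth^2))
  if (denom == 0) stopf("relative RMSE undefined for an all-zero truth image")
  sqrt(sum((recon - truth)^2)) / denom
}

#' Relative root-mean-square reconstruction error
#'
#' \eqn{\|g - g_{true}\|_2 / \|g_{true}\|_2}, the standard phantom-study
#' error metric used throughout the reconstruction experiments.
#'
#' @param recon,truth [image_grid()]s of identical dimensions; `truth` must
#'   not be all zero.
#' @return A single non-negative number.
#' @export
reconstruction_error <- function(recon, truth) {
  if (!identical(dim(recon), dim(truth)))
    stopf("reconstruction and truth dimensions differ")
  rel_rmse_vec(as.vector(recon), as.vector(truth))
}

#' Poisson log-likelihood of an image under a sinogram
#'
#' \eqn{\sum_i [y_i \log \max(\hat y_i, \epsilon) - \hat y_i]} up to an
#' image-independent constant, with \eqn{\hat y = A g}. MLEM never decreases
#' this quantity (the EM monotonicity property).
#'
#' @param y A [sinogram()].
#' @param sm The [build_system_matrix()].
#' @param g A non-negative [image_grid()].
#' @param epsilon Guard inside the logarithm.
#' @return A single number.
#' @export
poisson_log_likelihood <- function(y, sm, g, epsilon = 1e-12) {
  stopifnot(inherits(y, "sinogram"), inherits(sm, "system_matrix"))
  if (min(g) < 0) stopf("image must be non-negative")
  yv <- ray_vector(y)
  yhat <- as.numeric(sm$A %*% as.vector(g))
  sum(yv * log(pmax(yhat, epsilon)) - yhat)
}
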