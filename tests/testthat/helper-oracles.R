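# Independent reference implementations used as oracles. These deliberately
# avoid the package's sparse code paths: dense loops and fine numerical
# sampling only.

# Line-integral projection by fine sampling: walks each ray in steps of
# `step` pixels, accumulating the pixel value under the sample point
# (nearest-neighbor lookup). Converges to the exact intersection-length
# model as step -> 0. Same geometric conventions as the package projector.
sample_radon <- function(img, angles_deg, n_det, step = 1 / 16) {
  n_row <- nrow(img); n_col <- ncol(img)
  xmin <- -n_col / 2; ymax <- n_row / 2
  half <- (n_row + n_col)
  out <- matrix(0, length(angles_deg), n_det)
  for (ai in seq_along(angles_deg)) {
    th <- angles_deg[ai] * pi / 180
    u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
    for (d in seq_len(n_det)) {
      t <- (d - (n_det + 1) / 2)
      s <- seq(-half, half, by = step)
      x <- t * u[1] + s * v[1]
      y <- t * u[2] + s * v[2]
      c0 <- floor(x - xmin) + 1L
      r0 <- floor(ymax - y) + 1L
      ok <- c0 >= 1L & c0 <= n_col & r0 >= 1L & r0 <= n_row
      out[ai, d] <- sum(img[cbind(r0[ok], c0[ok])]) * step
    }
  }
  out
}

# Dense double-loop OSEM: explicit per-ray forward sums and per-pixel
# correction sums on a dense copy of the system matrix.
dense_osem <- function(y_vec, A_dense, subsets_rows, n_iter, g0, eps = 1e-12) {
  g <- g0
  for (it in seq_len(n_iter)) {
    for (rows in subsets_rows) {
      yhat <- numeric(length(rows))
      for (k in seq_along(rows))
        yhat[k] <- sum(A_dense[rows[k], ] * g)
      r <- y_vec[rows] / pmax(yhat, eps)
      for (j in seq_along(g)) {
        qs <- A_dense[rows, j]
        sens <- sum(qs)
        if (sens > 0) g[j] <- g[j] * sum(qs * r) / sens
      }
    }
  }
  g
}

# Angle-major ray row indices for a set of angle indices.
subset_rows <- function(idx, nd) {
  idx <- as.integer(idx); nd <- as.integer(nd)
  as.vector(vapply(idx, function(a) (a - 1L) * nd + seq_len(nd), integer(nd)))
}

# Exhaustive pairwise Mann-Whitney AUC with half credit for ties.
mann_whitney_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# shared small reconstruction fixture: 32x32 phantom, 36 angles at 5 deg
.fixture_env <- new.env(parent = emptyenv())
fixture32 <- function() {
  if (is.null(.fixture_env$f32)) {
    ph <- generate_shepp_logan(32)
    geom <- make_geometry(5, 180, default_detector_count(32))
    sm <- build_system_matrix(geom, ph)
    .fixture_env$f32 <- list(ph = ph, geom = geom, sm = sm,
                             y = forward_project(sm, ph))
  }
  .fixture_env$f32
}
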