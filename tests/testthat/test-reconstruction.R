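test_that("initial image is uniform, strictly positive, shape-preserving", {
  g <- init_image(image_grid(matrix(0, 256, 256)))
  expect_true(all(g == 1))
  expect_equal(dim(g), c(256L, 256L))
  expect_equal(unclass(init_image(image_grid(matrix(5, 2, 2)))),
               matrix(1, 2, 2), ignore_attr = TRUE)
})

test_that("subset partitions are disjoint, covering and balanced", {
  for (case in list(c(180, 6), c(180, 180), c(60, 6), c(36, 4), c(8, 2))) {
    for (strat in c("sequential", "optimized")) {
      p <- partition_subsets(case[1], case[2], strat)
      expect_equal(p$L, case[1] / case[2])
      all_idx <- sort(unlist(p$subsets))
      expect_identical(all_idx, seq_len(case[1]))          # covering, disjoint
      expect_true(all(lengths(p$subsets) == case[2]))      # balanced
      # uniform angular coverage: within-subset stride equals L
      for (s in p$subsets)
        if (length(s) > 1) expect_true(all(diff(s) == p$L))
      expect_identical(sort(p$order), seq_len(p$L))
    }
  }
  expect_error(partition_subsets(180, 7), "divisor")
})

test_that("optimized ordering maximizes successive angular separation", {
  p <- partition_subsets(8, 2, "optimized")
  expect_identical(p$order, c(1L, 3L, 2L, 4L))
  expect_identical(partition_subsets(8, 2, "sequential")$order, 1:4)
  # single subset: degenerate order
  expect_identical(partition_subsets(12, 12, "optimized")$order, 1L)
  # successive lead separations under optimized ordering are never smaller
  # than under sequential ordering (circular metric on the lead circle)
  for (L in c(4, 10, 30)) {
    p <- partition_subsets(6 * L, 6, "optimized")
    leads <- p$order - 1
    d <- abs(diff(leads)) %% L
    expect_true(all(pmin(d, L - d) >= 1))
    expect_gt(mean(pmin(d, L - d)), 1)  # sequential ordering averages exactly 1
  }
})

test_that("residuals follow the guarded ratio definition", {
  expect_equal(compute_residual(c(1, 2, 3), c(1, 2, 3)), c(1, 1, 1))
  expect_equal(compute_residual(c(2, 4), c(1, 2)), c(2, 2))
  expect_equal(compute_residual(0, 0), 0)  # 0 / epsilon
  expect_error(compute_residual(-1, 1), "non-negative")
  expect_error(compute_residual(1:3, 1:2), "length")
})

test_that("correction factors match a dense double-loop oracle", {
  f <- fixture32()
  rows <- c(1:f$geom$n_detectors, 1:f$geom$n_detectors + 5 * f$geom$n_detectors)
  Ad <- as.matrix(f$sm$A)
  set.seed(7)
  res <- runif(length(rows)) + 0.5
  corr <- compute_correction(f$sm, res, c(1, 6))
  oracle <- rep(1, ncol(Ad))
  for (j in seq_len(ncol(Ad))) {
    qs <- Ad[rows, j]
    if (sum(qs) > 0) oracle[j] <- sum(qs * res) / sum(qs)
  }
  expect_equal(as.vector(corr), oracle, tolerance = 1e-13)
  # fixed points of the correction
  ones <- compute_correction(f$sm, rep(1, length(rows)), c(1, 6))
  expect_equal(unique(round(as.vector(ones), 12)), 1)
  twos <- compute_correction(f$sm, rep(2, length(rows)), c(1, 6))
  covered <- Matrix::colSums(f$sm$A[rows, ]) > 0
  expect_true(all(abs(as.vector(twos)[covered] - 2) < 1e-12))
  expect_error(compute_correction(f$sm, numeric(0), integer(0)), "at least one")
})

test_that("multiplicative update preserves positivity and zeros", {
  st <- osemeat:::new_recon_state(image_grid(matrix(c(1, 2, 0, 4), 2)))
  up <- apply_update(st, image_grid(matrix(c(3, 0.5, 7, 1), 2)))
  expect_equal(unclass(up$image), matrix(c(3, 1, 0, 4), 2), ignore_attr = TRUE)
  expect_equal(up$sub_iterations_done, 1L)
  expect_error(apply_update(st, image_grid(matrix(-1, 2, 2))), "non-negative")
})

test_that("single-subset OSEM is exactly MLEM", {
  f <- fixture32()
  cfg <- recon_config(4)
  os <- osem_reconstruct(f$y, f$sm, partition_subsets(36, 36), cfg, truth = f$ph)
  ml <- mlem_reconstruct(f$y, f$sm, cfg, truth = f$ph)
  expect_identical(unclass(os$image), unclass(ml$image))
  expect_identical(os$error_history, ml$error_history)
})

test_that("consistent data with the truth as start is a fixed point", {
  f <- fixture32()
  st <- osem_reconstruct(f$y, f$sm, partition_subsets(36, 6, "optimized"),
                         recon_config(10, track_loglik = FALSE),
                         initial = f$ph)
  expect_lt(max(abs(unclass(st$image) - unclass(f$ph))), 1e-10)
})

test_that("sparse OSEM equals the dense double-loop oracle on 32x32", {
  f <- fixture32()
  part <- partition_subsets(36, 6, "optimized")
  st <- osem_reconstruct(f$y, f$sm, part,
                         recon_config(5, track_loglik = FALSE))
  nd <- f$geom$n_detectors
  oracle <- dense_osem(as.vector(t(f$y$values)), as.matrix(f$sm$A),
                       lapply(part$order, function(m) subset_rows(part$subsets[[m]], nd)),
                       n_iter = 5, g0 = rep(1, 32 * 32))
  expect_equal(as.vector(st$image), oracle, tolerance = 1e-10)
})

test_that("MLEM never decreases the Poisson log-likelihood", {
  f <- fixture32()
  # noiseless data
  ml <- mlem_reconstruct(f$y, f$sm, recon_config(12))
  dll <- diff(ml$loglik_history)
  expect_true(all(dll >= -1e-9 * abs(ml$loglik_history[-1])))
  # Poisson-noisy data (any non-negative sinogram)
  set.seed(4)
  ynoisy <- sinogram(matrix(rpois(length(f$y$values), 30 * f$y$values) / 30,
                            nrow(f$y$values)), f$geom)
  mln <- mlem_reconstruct(ynoisy, f$sm, recon_config(12))
  dn <- diff(mln$loglik_history)
  expect_true(all(dn >= -1e-9 * abs(mln$loglik_history[-1])))
})

test_that("reconstruction error decreases with iterations on noiseless data", {
  f <- fixture32()
  st <- osem_reconstruct(f$y, f$sm, partition_subsets(36, 6, "optimized"),
                         recon_config(20, track_loglik = FALSE), truth = f$ph)
  expect_lt(st$error_history[20], st$error_history[1])
  expect_equal(length(st$error_history), st$k)
})

test_that("relative RMSE behaves as the documented metric", {
  a <- image_grid(matrix(c(1, 2, 3, 4), 2))
  expect_equal(reconstruction_error(a, a), 0)
  expect_equal(reconstruction_error(image_grid(2 * unclass(a)), a), 1)
  # hand case: recon = truth + 1 everywhere
  b <- image_grid(unclass(a) + 1)
  expect_equal(reconstruction_error(b, a), 2 / sqrt(30))
  expect_error(reconstruction_error(a, image_grid(matrix(0, 2, 2))),
               "all-zero")
})

test_that("Poisson log-likelihood peaks at the consistent image scale", {
  f <- fixture32()
  lls <- vapply(c(0.5, 0.9, 1, 1.1, 2), function(t)
    poisson_log_likelihood(f$y, f$sm, image_grid(t * unclass(f$ph))), 0)
  expect_equal(which.max(lls), 3L)
  # matches the direct formula, and the guard is inactive for positive data
  yv <- as.vector(t(f$y$values))
  yhat <- as.numeric(f$sm$A %*% as.vector(f$ph))
  direct <- sum(yv * log(pmax(yhat, 1e-12)) - yhat)
  expect_equal(poisson_log_likelihood(f$y, f$sm, f$ph), direct)
  expect_equal(poisson_log_likelihood(f$y, f$sm, f$ph, epsilon = 2e-12),
               direct)
})

test_that("configuration guards reject invalid epsilon and iteration counts", {
  expect_error(recon_config(0), "positive")
  expect_error(recon_config(5, epsilon = 0), "epsilon")
  expect_error(recon_config(5, epsilon = 1e-3), "epsilon")
})
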