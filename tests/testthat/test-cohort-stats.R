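test_that("the cohort generator is deterministic and well-formed", {
  p <- cohort_params(seed = 5)
  c1 <- generate_cohort(p); c2 <- generate_cohort(p)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 42 + 68)
  expect_equal(sum(c1$chd), 68)
  expect_true(all(c1$eat_ml >= 0))
  expect_true(all(c1$gensini >= 0))
  expect_true(all(c1$sex %in% 0:1) && all(c1$smoking %in% 0:1))
  expect_true(all(c1$nscv_category[c1$chd == 0] == "none"))
  expect_true(all(c1$nscv_category[c1$chd == 1] != "none"))
})

test_that("risk factors are shifted upward in the CHD group in expectation", {
  coh <- generate_cohort(cohort_params(n_control = 5000, n_chd = 5000,
                                       seed = 11))
  for (f in c("age", "smoking", "hypertension", "diabetes", "eat_ml")) {
    expect_gt(mean(coh[[f]][coh$chd == 1]), mean(coh[[f]][coh$chd == 0]))
  }
})

test_that("copula rank correlations are hit (and switched off) as requested", {
  coh <- generate_cohort(cohort_params(n_chd = 20000, seed = 2))
  chd <- coh[coh$chd == 1, ]
  expect_lt(abs(spearman_cor(chd$eat_ml, chd$gensini)$r - 0.327), 0.02)
  expect_gt(spearman_cor(chd$eat_ml, as.integer(chd$nscv_category))$r, 0.25)
  null <- generate_cohort(cohort_params(n_chd = 10000, rho_eat_gensini = 0,
                                        seed = 3))
  nchd <- null[null$chd == 1, ]
  expect_lt(abs(spearman_cor(nchd$eat_ml, nchd$gensini)$r), 0.02)
  expect_error(generate_cohort(cohort_params(rho_eat_gensini = 0.95,
                                             rho_eat_nscv = -0.95,
                                             rho_gensini_nscv = 0.9)),
               "positive-definite")
})

test_that("logistic fit reports Wald inference with definitional OR and CI", {
  coh <- generate_cohort(cohort_params(n_control = 400, n_chd = 400, seed = 8))
  fit <- logistic_fit(coh)
  expect_true(fit$converged)
  tab <- fit$table
  expect_equal(tab$OR, exp(tab$B))
  expect_equal(tab$ci_lower, exp(tab$B - 1.96 * tab$SE))
  expect_equal(tab$ci_upper, exp(tab$B + 1.96 * tab$SE))
  expect_equal(tab$wald, (tab$B / tab$SE)^2)
  expect_equal(tab$p, pchisq(tab$wald, 1, lower.tail = FALSE))
  # a covariate independent of the outcome sits within 3 SE of zero
  set.seed(31)
  coh$noise <- rnorm(nrow(coh))
  fit2 <- logistic_fit(coh, covariates = c("eat_ml", "noise"))
  nrow_ <- fit2$table[fit2$table$term == "noise", ]
  expect_lt(abs(nrow_$B), 3 * nrow_$SE)
})

test_that("separation and singular designs are flagged, not reported silently", {
  sep <- data.frame(chd = rep(0:1, each = 10), x = 1:20)
  fit <- logistic_fit(sep, covariates = "x")
  expect_true(fit$separation)
  expect_false(fit$converged)
  dup <- generate_cohort(cohort_params(seed = 4))
  dup$eat_copy <- dup$eat_ml
  expect_error(logistic_fit(dup, covariates = c("eat_ml", "eat_copy")),
               "singular")
  const <- generate_cohort(cohort_params(seed = 4))
  const$flat <- 1
  expect_error(logistic_fit(const, covariates = "flat"), "constant")
})

test_that("Spearman correlation matches rank arithmetic and cor.test", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$r, 1)
  expect_equal(spearman_cor(1:10, -(1:10)^3)$r, -1)
  s <- spearman_cor(1:5, c(1, 3, 2, 5, 4))
  expect_equal(s$r, 0.8)  # 1 - 6*4 / (5*24)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  # invariant under strictly monotone transforms
  set.seed(12)
  x <- rnorm(50); y <- x + rnorm(50)
  expect_equal(spearman_cor(exp(x), y)$r, spearman_cor(x, y)$r)
  expect_equal(spearman_cor(x, qlogis(pnorm(y)))$r, spearman_cor(x, y)$r)
  # agreement with the standard implementation, ties included
  set.seed(13)
  xt <- sample(1:8, 40, replace = TRUE); yt <- xt + sample(1:5, 40, TRUE)
  ref <- suppressWarnings(stats::cor.test(xt, yt, method = "spearman"))
  mine <- spearman_cor(xt, yt)
  expect_equal(mine$r, unname(ref$estimate))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-6)
})

test_that("ROC analysis sweeps thresholds and maximizes Youden's J", {
  r <- roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1.0)
  expect_true(r$optimal_threshold > 2 && r$optimal_threshold <= 3)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  # separated vs permuted
  set.seed(14)
  sc <- c(rnorm(300), rnorm(300, 10)); lb <- rep(0:1, each = 300)
  expect_equal(roc_analysis(sc, lb)$auc, 1.0)
  expect_lt(abs(roc_analysis(sc, sample(lb))$auc - 0.5), 0.05)
  expect_error(roc_analysis(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("trapezoidal AUC equals the pairwise Mann-Whitney count", {
  set.seed(15)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    scores <- sample(1:12, n, replace = TRUE)  # heavy ties
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) == 0 || sum(labels) == n) labels[1:2] <- c(0, 1)
    r <- roc_analysis(scores, labels)
    expect_equal(r$auc, mann_whitney_auc(scores, labels), tolerance = 1e-12)
    # complement invariant
    expect_equal(r$auc + roc_analysis(scores, 1 - labels)$auc, 1)
  }
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(16)
  scores <- rnorm(80); labels <- rbinom(80, 1, plogis(scores))
  if (sum(labels) %in% c(0, 80)) labels[1:2] <- c(0, 1)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_analysis(scores, labels)$auc, ref, tolerance = 1e-12)
})

test_that("group comparison picks Welch t or corrected chi-square", {
  # identical samples in both groups: zero statistic, p = 1
  same <- data.frame(chd = rep(0:1, each = 20), v = rep(rnorm(20, 5), 2))
  gc0 <- group_compare(same, "v")
  expect_equal(gc0$statistic, 0)
  expect_equal(gc0$p, 1)
  # strongly shifted means are detected
  set.seed(17)
  shift <- data.frame(chd = rep(0:1, each = 100),
                      v = c(rnorm(100, 0, 1), rnorm(100, 5, 1)))
  expect_lt(group_compare(shift, "v")$p, 0.001)
  # 2x2 hand case: 20/80 vs 40/60 with continuity correction
  bin <- data.frame(chd = rep(0:1, c(100, 100)),
                    v = c(rep(1:0, c(20, 80)), rep(1:0, c(40, 60))))
  gcb <- group_compare(bin, "v")
  expect_equal(gcb$type, "binary")
  n <- 200; ad_bc <- abs(20 * 60 - 80 * 40)
  hand <- n * (ad_bc - n / 2)^2 / (100 * 100 * 60 * 140)
  expect_equal(gcb$statistic, hand)
})
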