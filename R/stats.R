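#' Multivariable logistic risk model
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()]) of a binary outcome on a set of covariates,
#' reported the way clinical risk-factor tables are: per covariate the
#' log-odds coefficient B, its standard error from the inverse observed
#' information, the Wald statistic (B/SE)^2 with its chi-square p-value, and
#' the odds ratio exp(B) with 95 percent CI exp(B +/- 1.96 SE). Perfect or
#' quasi-perfect separation is flagged as non-convergence instead of being
#' reported silently.
#'
#' @param cohort Data frame of patients.
#' @param outcome Name of the binary 0/1 outcome column (e.g. `"chd"`).
#' @param covariates Character vector of covariate column names.
#' @return An object of class `logistic_result`: list with `table` (data
#'   frame: term, B, SE, wald, OR, ci_lower, ci_upper, p), `converged`,
#'   `separation`, `n_iterations`, `n`.
#' @export
logistic_fit <- function(cohort, outcome = "chd",
                         covariates = c("eat_ml", "uric_acid", "age", "bmi",
                                        "sex", "smoking", "hypertension",
                                        "diabetes")) {
  stopifnot(is.data.frame(cohort))
  miss <- setdiff(c(outcome, covariates), names(cohort))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  yv <- cohort[[outcome]]
  if (!all(yv %in% c(0, 1))) stopf("outcome must be binary 0/1")
  for (v in covariates)
    if (length(unique(cohort[[v]])) < 2L)
      stopf("covariate `%s` is constant", v)
  if (nrow(cohort) <= length(covariates) + 1L)
    stopf("need more observations than parameters")
  f <- stats::reformulate(covariates, response = outcome)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(f, family = binomial(), data = cohort),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (qr(stats::model.matrix(fit))$rank < length(coef(fit)))
    stopf("singular design matrix: covariates are linearly dependent")
  B <- coef(fit)
  SE <- sqrt(diag(vcov(fit)))
  wald <- (B / SE)^2
  tab <- data.frame(term = names(B), B = unname(B), SE = unname(SE),
                    wald = unname(wald), OR = unname(exp(B)),
                    ci_lower = unname(exp(B - 1.96 * SE)),
                    ci_upper = unname(exp(B + 1.96 * SE)),
                    p = unname(pchisq(wald, df = 1, lower.tail = FALSE)))
  structure(list(table = tab, converged = fit$converged && !sep,
                 separation = sep, n_iterations = fit$iter,
                 n = nrow(cohort)),
            class = "logistic_result")
}

#' @export
print.logistic_result <- function(x, ...) {
  cat(sprintf("<logistic_result> n = %d, %s in %d IRLS iterations\n", x$n,
              if (x$converged) "converged" else "DID NOT CONVERGE (separation?)",
              x$n_iterations))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Spearman rank correlation
#'
#' r is the Pearson correlation of mid-ranks (average ranks on ties); the
#' two-sided p-value uses the t approximation with n - 2 degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3; neither may be
#'   constant.
#' @return An object of class `spearman_result`: list with `r`, `p`, `n`.
#' @examples
#' spearman_cor(1:5, c(1, 3, 2, 5, 4))$r  # 0.8
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  n <- length(x)
  if (n < 3) stopf("need at least 3 paired observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stopf("Spearman correlation is undefined for a constant vector")
  r <- cor(rank(x), rank(y))
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(r = r, p = p, n = n), class = "spearman_result")
}

#' @export
print.spearman_result <- function(x, ...) {
  cat(sprintf("<spearman_result> r = %.3f, p = %.4g, n = %d\n", x$r, x$p, x$n))
  invisible(x)
}

#' Empirical ROC analysis
#'
#' Sweeps every distinct score as a positivity threshold (predict positive
#' when score >= threshold), traces the empirical ROC curve, integrates the
#' AUC by the trapezoidal rule (equal to the Mann-Whitney probability with
#' half credit for ties), and picks the operating threshold maximizing
#' Youden's J = sensitivity + specificity - 1, ties resolved at the lower
#' threshold.
#'
#' @param scores Numeric predictor (higher = more disease-like).
#' @param labels Binary 0/1 outcome vector; both classes must be present.
#' @return An object of class `roc_result`: list with `auc`, `points` (data
#'   frame threshold/fpr/tpr including the two trivial endpoints),
#'   `optimal_threshold`, `sensitivity`, `specificity`, `youden_j`.
#' @export
roc_analysis <- function(scores, labels) {
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  if (!all(labels %in% c(0, 1))) stopf("labels must be binary 0/1")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stopf("both classes must be present")
  thr <- sort(unique(scores))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n_neg, 0)
  pts <- data.frame(threshold = c(-Inf, thr, Inf),
                    fpr = c(1, fpr, 0), tpr = c(1, tpr, 0))
  pts <- pts[order(pts$fpr, pts$tpr), ]
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  j <- tpr - fpr
  best <- which(j == max(j))
  best <- best[which.min(thr[best])]
  structure(list(auc = auc, points = pts, optimal_threshold = thr[best],
                 sensitivity = tpr[best], specificity = 1 - fpr[best],
                 youden_j = j[best]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f; Youden threshold %.4g (sens %.3f, spec %.3f)\n",
              x$auc, x$optimal_threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' Two-group comparison of a cohort field
#'
#' Welch's t-test for numeric fields; chi-square test with continuity
#' correction on the 2 x 2 table for binary fields. Groups are defined by
#' the binary `chd` column.
#'
#' @param cohort Cohort data frame with a `chd` column.
#' @param field Name of the column to compare.
#' @return An object of class `group_comparison`: list with `field`,
#'   `type` ("numeric" or "binary"), per-group `summary` (mean/sd or
#'   count/proportion), `statistic`, `p`.
#' @export
group_compare <- function(cohort, field) {
  stopifnot(is.data.frame(cohort), "chd" %in% names(cohort))
  if (!field %in% names(cohort)) stopf("no column `%s` in the cohort", field)
  x <- cohort[[field]]
  g0 <- x[cohort$chd == 0]; g1 <- x[cohort$chd == 1]
  if (length(g0) == 0 || length(g1) == 0) stopf("both groups must be non-empty")
  if (all(x %in% c(0, 1))) {
    tab <- rbind(control = c(sum(g0 == 1), sum(g0 == 0)),
                 chd = c(sum(g1 == 1), sum(g1 == 0)))
    ts <- suppressWarnings(chisq.test(tab, correct = TRUE))
    structure(list(field = field, type = "binary",
                   summary = data.frame(group = c("control", "chd"),
                                        n = c(length(g0), length(g1)),
                                        proportion = c(mean(g0), mean(g1))),
                   statistic = unname(ts$statistic), p = ts$p.value),
              class = "group_comparison")
  } else {
    ts <- t.test(g1, g0)
    structure(list(field = field, type = "numeric",
                   summary = data.frame(group = c("control", "chd"),
                                        n = c(length(g0), length(g1)),
                                        mean = c(mean(g0), mean(g1)),
                                        sd = c(stats::sd(g0), stats::sd(g1))),
                   statistic = unname(ts$statistic), p = ts$p.value),
              class = "group_comparison")
  }
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (%s): statistic %.4g, p = %.4g\n",
              x$field, x$type, x$statistic, x$p))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
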