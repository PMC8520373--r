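#' Synthetic cohort parameters
#'
#' Calibration of the synthetic two-group cohort. The EAT group parameters
#' default to the reported clinical calibration: control
#' Normal(124.50, 26.72^2) mL and CHD Normal(159.41, 38.51^2) mL, truncated
#' at zero. Within the CHD group, Gensini score and NSCV are tied to EAT by
#' a Gaussian copula with the stated Spearman rank correlations.
#'
#' @param n_control,n_chd Group sizes (defaults 42 / 68, the clinical group
#'   sizes).
#' @param eat_mean_control,eat_sd_control,eat_mean_chd,eat_sd_chd EAT
#'   distribution parameters in mL.
#' @param rho_eat_gensini,rho_eat_nscv Target Spearman rank correlations of
#'   EAT with Gensini score and with NSCV in the CHD group (defaults 0.327
#'   and 0.416).
#' @param rho_gensini_nscv Rank correlation between Gensini and NSCV (both
#'   measure lesion burden; default 0.5).
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_control = 42, n_chd = 68,
                          eat_mean_control = 124.50, eat_sd_control = 26.72,
                          eat_mean_chd = 159.41, eat_sd_chd = 38.51,
                          rho_eat_gensini = 0.327, rho_eat_nscv = 0.416,
                          rho_gensini_nscv = 0.5, seed = 1) {
  if (n_control < 2 || n_chd < 2) stopf("need at least 2 patients per group")
  if (eat_sd_control <= 0 || eat_sd_chd <= 0) stopf("EAT sds must be positive")
  for (r in c(rho_eat_gensini, rho_eat_nscv, rho_gensini_nscv))
    if (abs(r) >= 1) stopf("rank correlations must lie in (-1, 1)")
  structure(as.list(environment()), class = "cohort_params")
}

# Spearman rank correlation -> Gaussian copula correlation
copula_rho <- function(rho_s) 2 * sin(pi * rho_s / 6)

# inverse-CDF sample of Normal(mean, sd) truncated at 0, from uniforms
rtruncnorm0 <- function(u, mean, sd) {
  p0 <- pnorm(0, mean, sd)
  qnorm(p0 + u * (1 - p0), mean, sd)
}

#' Generate a synthetic two-group cohort
#'
#' Draws a control group and a CHD group with the calibration in `params`.
#' EAT volumes are zero-truncated normal per group. For CHD patients,
#' Gensini score and NSCV category are generated jointly with EAT through a
#' Gaussian copula whose correlations are set (via the
#' \eqn{2\sin(\pi\rho_s/6)} map) to hit the target Spearman correlations;
#' Gensini uses a gamma severity margin and NSCV cuts its latent uniform at
#' the observed single/double/multi case mix. Controls receive small
#' sub-threshold Gensini scores and NSCV "none". Risk covariates (age, sex,
#' BMI, uric acid, smoking, hypertension, diabetes) are drawn with
#' group-shifted means/prevalences so that age, smoking, hypertension,
#' diabetes and EAT are higher in the CHD group in expectation, while BMI,
#' sex and uric acid do not differ.
#'
#' @param params A [cohort_params()].
#' @return A data frame (one row per patient) with columns `group`, `chd`,
#'   `age`, `sex`, `bmi`, `uric_acid`, `smoking`, `hypertension`,
#'   `diabetes`, `eat_ml`, `gensini`, `nscv_category`.
#' @examples
#' coh <- generate_cohort(cohort_params(seed = 7))
#' tapply(coh$eat_ml, coh$group, mean)
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  Sigma <- matrix(c(
    1, copula_rho(p$rho_eat_gensini), copula_rho(p$rho_eat_nscv),
    copula_rho(p$rho_eat_gensini), 1, copula_rho(p$rho_gensini_nscv),
    copula_rho(p$rho_eat_nscv), copula_rho(p$rho_gensini_nscv), 1),
    3, 3)
  ch <- tryCatch(chol(Sigma), error = function(e)
    stopf("the requested rank correlations give a non-positive-definite copula"))

  with_seed(p$seed, {
    n0 <- p$n_control; n1 <- p$n_chd
    # control group
    eat0 <- rtruncnorm0(runif(n0), p$eat_mean_control, p$eat_sd_control)
    gensini0 <- round(qgamma(runif(n0), shape = 0.8, scale = 3), 1)
    # CHD group: copula-linked EAT, Gensini, NSCV
    z <- matrix(rnorm(3 * n1), n1, 3) %*% ch
    u <- pnorm(z)
    eat1 <- rtruncnorm0(u[, 1], p$eat_mean_chd, p$eat_sd_chd)
    gensini1 <- round(qgamma(u[, 2], shape = 1.5, scale = 20), 1)
    # observed single:double:multi case mix 10:19:19
    cuts <- cumsum(c(10, 19) / 48)
    nscv1 <- cut(u[, 3], breaks = c(0, cuts, 1),
                 labels = c("single", "double", "multi"),
                 include.lowest = TRUE)
    covars <- function(n, age_mean, age_sd, p_male, p_smoke, p_htn, p_dm) {
      data.frame(
        age = rnorm(n, age_mean, age_sd),
        sex = rbinom(n, 1, p_male),
        bmi = rnorm(n, 24.5, 3.2),
        uric_acid = rnorm(n, 340, 80),
        smoking = rbinom(n, 1, p_smoke),
        hypertension = rbinom(n, 1, p_htn),
        diabetes = rbinom(n, 1, p_dm))
    }
    ctrl <- covars(n0, 59.85, 7.67, 28 / 42, 0.25, 0.30, 0.15)
    chd <- covars(n1, 61.67, 6.28, 42 / 68, 0.45, 0.50, 0.30)
    rbind(
      data.frame(group = "control", chd = 0L, ctrl, eat_ml = eat0,
                 gensini = gensini0,
                 nscv_category = factor("none", levels = c("none", "single",
                                                           "double", "multi"))),
      data.frame(group = "chd", chd = 1L, chd, eat_ml = eat1,
                 gensini = gensini1,
                 nscv_category = factor(as.character(nscv1),
                                        levels = c("none", "single",
                                                   "double", "multi"))))
  })
}

#' Write / read a cohort CSV
#'
#' @param cohort Cohort data frame from [generate_cohort()].
#' @param path CSV file path.
#' @return `read_cohort_csv` returns the cohort data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("nscv_category" %in% names(df))
    df$nscv_category <- factor(df$nscv_category,
                               levels = c("none", "single", "double", "multi"))
  df
}
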