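# least-squares plumbing shared by the estimators ------------------------

# model matrix for the named columns, factors expanded, no intercept column
design_matrix <- function(data, cols) {
  d <- as.data.frame(data[, cols, drop = FALSE])
  mm <- stats::model.matrix(~ ., data = d)
  mm[, -1, drop = FALSE]
}

# intercept-included least squares with classical (homoskedastic) inference
lsfit_basic <- function(y, x) {
  xx <- cbind(`(Intercept)` = 1, x)
  qr_x <- qr(xx)
  if (qr_x$rank < ncol(xx)) {
    kappa_x <- kappa(xx, exact = FALSE)
    abort(sprintf("Collinear design (rank %d < %d columns, condition number %.3g).",
                  qr_x$rank, ncol(xx), kappa_x))
  }
  beta <- qr.coef(qr_x, y)
  fitted <- drop(xx %*% beta)
  resid <- y - fitted
  n <- length(y); p <- ncol(xx)
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  df_residual <- n - p
  sigma2 <- rss / df_residual
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  tval <- beta / se
  coef_table <- cbind(estimate = beta, se = se, statistic = tval,
                      p_value = 2 * pt(-abs(tval), df_residual))
  rownames(coef_table) <- colnames(xx)
  list(coefficients = beta, fitted = fitted, residuals = resid,
       rss = rss, r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
       df_residual = df_residual, sigma2 = sigma2,
       xtx_inv = xtx_inv, coef_table = coef_table, n = n)
}

new_mr_fit <- function(beta, se, p_value, n, method, model = "crude",
                       term = NULL, first_stage = NULL, weak = FALSE) {
  structure(
    list(beta = beta, se = se,
         ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
         p_value = p_value, n = n, method = method, model = model,
         term = term, first_stage = first_stage,
         weak_instrument = weak),
    class = "mr_fit"
  )
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("%s (%s): beta %.3f (95%% CI %.3f, %.3f), p %.3g, n %d%s\n",
              x$method, x$model, x$beta, x$ci_low, x$ci_high, x$p_value, x$n,
              if (isTRUE(x$weak_instrument)) " [weak instrument]" else ""))
  invisible(x)
}

#' Ordinary least-squares association
#'
#' Intercept-included linear regression of the outcome on the exposure (plus
#' optional covariates) with classical homoskedastic standard errors and a
#' t-based p-value — the conventional observational estimate against which
#' the instrumental-variable estimate is compared. The 95% CI is
#' `beta +/- 1.959964 * se`.
#'
#' @param data Data frame holding all columns.
#' @param outcome,exposure Column names (typically standardized z-scores, so
#'   `beta` is in SD per SD).
#' @param covariates Optional character vector of covariate column names.
#' @param model Label stored on the result (`"crude"` or `"adjusted"`).
#' @return An `mr_fit` with `beta`, `se`, `ci_low`, `ci_high`, `p_value`,
#'   `n`, `method = "OLS"`.
#' @export
ols_fit <- function(data, outcome, exposure, covariates = NULL,
                    model = if (length(covariates)) "adjusted" else "crude") {
  assert_columns(data, c(outcome, exposure, covariates))
  d <- complete_cases(data, c(outcome, exposure, covariates))
  x <- design_matrix(d, c(exposure, covariates))
  if (nrow(d) <= ncol(x) + 1) abort("Too few observations.")
  fit <- lsfit_basic(d[[outcome]], x)
  tt <- fit$coef_table[exposure, ]
  new_mr_fit(tt[["estimate"]], tt[["se"]], tt[["p_value"]], nrow(d),
             method = "OLS", model = model, term = exposure)
}

#' Two-stage least-squares causal estimate
#'
#' The instrumental-variable estimator: stage one regresses the exposure on
#' the instrument (and any exogenous covariates); stage two regresses the
#' outcome on the stage-one fitted exposure (and the same covariates). The
#' coefficient on fitted exposure is the causal estimate. Standard errors
#' follow the 2SLS convention: residuals are computed with the *observed*
#' exposure at the 2SLS coefficients, `sigma^2 = RSS / (n - p)`, and the
#' variance is `sigma^2 (Xhat' Xhat)^-1` — not the naive second-stage OLS
#' standard error. Exogenous covariates enter both stages.
#'
#' A first-stage F at or below 10 sets the weak-instrument flag; an F below
#' `f_floor` (default 1) is an error.
#'
#' @inheritParams ols_fit
#' @param instrument Instrument column name (SNP dosage or allele score).
#' @param f_floor Hard lower bound on the first-stage F.
#' @return An `mr_fit` with `method = "2SLS"` and the [first_stage_fit()]
#'   attached as `$first_stage`.
#' @export
tsls_fit <- function(data, outcome, exposure, instrument, covariates = NULL,
                     model = if (length(covariates)) "adjusted" else "crude",
                     f_floor = 1) {
  assert_columns(data, c(outcome, exposure, instrument, covariates))
  d <- complete_cases(data, c(outcome, exposure, instrument, covariates))
  fs <- first_stage_fit(d, exposure, instrument, covariates)
  fcheck <- if (length(covariates)) fs$partial_f else fs$f_statistic
  if (is.na(fcheck) || fcheck < f_floor) {
    abort(sprintf("First-stage F %.3f is below the hard floor %.1f.",
                  fcheck, f_floor))
  }
  z <- design_matrix(d, c(instrument, covariates))
  x_obs <- d[[exposure]]
  stage1 <- lsfit_basic(x_obs, z)
  xhat <- stage1$fitted
  covs_mm <- if (length(covariates)) design_matrix(d, covariates) else NULL
  x2 <- cbind(.fitted_exposure = xhat, covs_mm)
  y <- d[[outcome]]
  stage2 <- lsfit_basic(y, x2)
  beta <- stage2$coefficients
  n <- nrow(d); p <- length(beta)
  # IV residuals: observed exposure at the 2SLS coefficients
  x_struct <- cbind(`(Intercept)` = 1, .fitted_exposure = x_obs, covs_mm)
  resid_iv <- y - drop(x_struct %*% beta)
  sigma2 <- sum(resid_iv^2) / (n - p)
  se <- sqrt(pmax(diag(stage2$xtx_inv), 0) * sigma2)
  names(se) <- names(beta)
  b <- beta[[".fitted_exposure"]]
  s <- se[[".fitted_exposure"]]
  pval <- 2 * pt(-abs(b / s), n - p)
  new_mr_fit(b, s, pval, n, method = "2SLS", model = model, term = exposure,
             first_stage = fs, weak = fs$weak)
}

#' Wald ratio estimate
#'
#' Single-instrument IV estimate `cov(Z, Y) / cov(Z, X)`. On any fixed
#' dataset this equals the covariate-free [tsls_fit()] coefficient exactly;
#' it serves as an independent cross-check of the 2SLS algebra.
#'
#' @inheritParams tsls_fit
#' @return The scalar estimate.
#' @export
wald_ratio <- function(data, outcome, exposure, instrument) {
  assert_columns(data, c(outcome, exposure, instrument))
  d <- complete_cases(data, c(outcome, exposure, instrument))
  denom <- cov(d[[instrument]], d[[exposure]])
  if (abs(denom) < .Machine$double.eps^0.5) {
    abort("Instrument-exposure covariance is zero; Wald ratio undefined.")
  }
  cov(d[[instrument]], d[[outcome]]) / denom
}

#' Durbin-Wu-Hausman endogeneity test
#'
#' Tests whether the exposure is endogenous — i.e. whether the OLS and IV
#' estimates differ beyond sampling error. The primary form is the
#' control-function (augmented) regression: add the first-stage residual to
#' the outcome model and t-test its coefficient; it is always well defined.
#' The contrast form, `(b_IV - b_OLS)^2 / (se_IV^2 - se_OLS^2)` against
#' chi-square(1), is reported only when the variance difference is positive,
#' and suppressed with a note otherwise.
#'
#' @inheritParams tsls_fit
#' @return A `hausman_test` list: `statistic` (t of the control-function
#'   coefficient), `p_value`, `form = "augmented_regression"`, plus
#'   `contrast_statistic` / `contrast_p` (or `NA` with `note`).
#' @export
durbin_hausman <- function(data, outcome, exposure, instrument,
                           covariates = NULL) {
  assert_columns(data, c(outcome, exposure, instrument, covariates))
  d <- complete_cases(data, c(outcome, exposure, instrument, covariates))
  z <- design_matrix(d, c(instrument, covariates))
  stage1 <- lsfit_basic(d[[exposure]], z)
  d$.fs_resid <- stage1$residuals
  if (sd(d$.fs_resid) < 1e-12) {
    # instrument reproduces the exposure exactly: OLS and IV coincide and
    # there is no endogeneity information; statistic 0 by convention
    tt <- c(statistic = 0, p_value = 1)
  } else {
    x_aug <- design_matrix(d, c(exposure, covariates, ".fs_resid"))
    aug <- lsfit_basic(d[[outcome]], x_aug)
    tt <- aug$coef_table[".fs_resid", ]
  }

  iv <- tsls_fit(d, outcome, exposure, instrument, covariates)
  ols <- ols_fit(d, outcome, exposure, covariates)
  var_diff <- iv$se^2 - ols$se^2
  if (var_diff > 0) {
    cstat <- (iv$beta - ols$beta)^2 / var_diff
    cp <- pchisq(cstat, df = 1, lower.tail = FALSE)
    note <- NA_character_
  } else {
    cstat <- NA_real_; cp <- NA_real_
    note <- "contrast form suppressed: non-positive variance difference"
  }
  structure(
    list(statistic = tt[["statistic"]], p_value = tt[["p_value"]],
         form = "augmented_regression",
         contrast_statistic = cstat, contrast_p = cp, note = note,
         n = nrow(d)),
    class = "hausman_test"
  )
}

#' @export
print.hausman_test <- function(x, ...) {
  cat(sprintf("Durbin-Wu-Hausman (augmented regression): t = %.3f, p = %.4g, n = %d\n",
              x$statistic, x$p_value, x$n))
  if (!is.na(x$contrast_statistic)) {
    cat(sprintf("  contrast form: chi-square(1) = %.3f, p = %.4g\n",
                x$contrast_statistic, x$contrast_p))
  } else cat(" ", x$note, "\n")
  invisible(x)
}

#' Pearson partial correlation
#'
#' Correlation of two variables after removing the linear effect of the
#' covariates from each (Pearson correlation of the two residual vectors),
#' with a t-test on `n - k - 2` degrees of freedom where `k` is the number
#' of covariate regressors.
#'
#' @param data Data frame.
#' @param a,b Column names of the two variables.
#' @param covariates Optional character vector of covariate columns; empty
#'   gives the plain Pearson correlation.
#' @return A tibble with `r`, `statistic`, `p_value`, `n`, `df`.
#' @export
partial_correlation <- function(data, a, b, covariates = NULL) {
  assert_columns(data, c(a, b, covariates))
  d <- complete_cases(data, c(a, b, covariates))
  if (length(covariates)) {
    mm <- design_matrix(d, covariates)
    ra <- lsfit_basic(d[[a]], mm)$residuals
    rb <- lsfit_basic(d[[b]], mm)$residuals
    k <- ncol(mm)
  } else {
    ra <- d[[a]] - mean(d[[a]]); rb <- d[[b]] - mean(d[[b]])
    k <- 0
  }
  if (sd(ra) == 0 || sd(rb) == 0) abort("Zero residual variance; partial correlation undefined.")
  n <- nrow(d)
  df <- n - k - 2
  if (df < 1) abort("Too few observations for the partial correlation.")
  r <- cor(ra, rb)
  tstat <- r * sqrt(df / (1 - r^2))
  tibble::tibble(r = r, statistic = tstat,
                 p_value = 2 * pt(-abs(tstat), df), n = n, df = df)
}

#' Compare two correlations via Fisher's z transformation
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, referred to
#' the standard normal (two-sided) — used to compare the SUA-adiposity
#' correlation between men and women.
#'
#' @param r1,r2 Correlations (|r| < 1).
#' @param n1,n2 Group sizes (> 3).
#' @return A tibble with `z` and `p_value`.
#' @export
#' @examples
#' fisher_z_compare(0.33, 3251, 0.24, 2933)
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (any(abs(c(r1, r2)) >= 1)) abort("|r| must be < 1.")
  if (any(c(n1, n2) <= 3)) abort("Group sizes must exceed 3.")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble::tibble(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Sex-interaction test on stratified estimates
#'
#' `z = (beta_men - beta_women) / sqrt(se_men^2 + se_women^2)`, referred to
#' the standard normal (two-sided).
#'
#' @param beta_men,beta_women Stratified standardized coefficients, or
#'   `mr_fit` objects (their `beta`/`se` are used).
#' @param se_men,se_women Standard errors (> 0); ignored when fits are given.
#' @return A tibble with `z` and `p_value`.
#' @export
#' @examples
#' sex_interaction(0.5, 0.1, 0.3, 0.1)
sex_interaction <- function(beta_men, se_men = NULL, beta_women = NULL,
                            se_women = NULL) {
  if (inherits(beta_men, "mr_fit")) {
    fit_m <- beta_men; fit_w <- se_men %||% beta_women
    if (!inherits(fit_w, "mr_fit")) abort("Provide two mr_fit objects or four numbers.")
    beta_men <- fit_m$beta; se_men <- fit_m$se
    beta_women <- fit_w$beta; se_women <- fit_w$se
  }
  if (any(c(se_men, se_women) <= 0)) abort("Standard errors must be positive.")
  z <- (beta_men - beta_women) / sqrt(se_men^2 + se_women^2)
  tibble::tibble(z = z, p_value = 2 * pnorm(-abs(z)))
}
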