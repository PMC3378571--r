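#' Orient SNP dosages to count trait-raising alleles
#'
#' For each SNP, fits the simple regression of the trait on the dosage and
#' flips the coding (`d -> 2 - d`) when the slope is negative, so that after
#' orientation the counted allele is the one associated with higher trait
#' values (0 = homozygote for the non-risk allele, 2 = homozygote for the
#' risk allele). A zero slope keeps the input orientation. Orientation is
#' data-driven and therefore stratum-specific; re-orienting oriented data is
#' a no-op.
#'
#' @param data Data frame holding the trait and dosage columns.
#' @param trait Name of the (transformed) trait column.
#' @param snps Character vector of dosage column names.
#' @return A list with `data` (dosage columns flipped where needed) and
#'   `orientation`, a tibble with `snp_id`, `slope` (post-orientation) and
#'   `flipped`.
#' @export
orient_risk_alleles <- function(data, trait, snps) {
  assert_columns(data, c(trait, snps))
  y <- data[[trait]]
  orientation <- purrr::map_dfr(snps, function(s) {
    g <- data[[s]]
    ok <- !is.na(g) & !is.na(y)
    if (length(unique(g[ok])) < 2) {
      abort(sprintf("SNP `%s` is monomorphic in this sample; run QC first.", s))
    }
    slope <- cov(y[ok], g[ok]) / var(g[ok])
    tibble::tibble(snp_id = s, slope = slope, flipped = slope < 0)
  })
  for (i in seq_len(nrow(orientation))) {
    if (orientation$flipped[i]) {
      s <- orientation$snp_id[i]
      data[[s]] <- 2L - data[[s]]
      orientation$slope[i] <- -orientation$slope[i]
    }
  }
  list(data = tibble::as_tibble(data), orientation = orientation)
}

#' Additive allele score
#'
#' Sums oriented dosages over the instrument SNPs into an unweighted risk
#' allele count in `[0, 2k]` — for three SNPs, an ordinal score from 0 to 6.
#' Dosages must be complete (select complete cases upstream).
#'
#' @param data Data frame holding oriented dosage columns.
#' @param snps Character vector of dosage column names.
#' @param name Name of the score column to append.
#' @return `data` with the integer score column appended.
#' @export
#' @examples
#' build_score(data.frame(a = 0, b = 1, c = 2), c("a", "b", "c"))$score
build_score <- function(data, snps, name = "score") {
  assert_columns(data, snps)
  m <- as.matrix(data[, snps, drop = FALSE])
  if (anyNA(m)) abort("Missing dosages in score SNPs; apply complete_cases() first.")
  if (!all(m %in% 0:2)) abort("Dosages must be 0, 1 or 2.")
  data[[name]] <- as.integer(rowSums(m))
  tibble::as_tibble(data)
}

#' Collapse sparse low score categories
#'
#' Merges score categories 0, 1 and 2 into a single ordered level, as done
#' for descriptive trend displays when those cells are sparse. The collapsed
#' variable is for trend tables only; model fitting uses the raw score.
#'
#' @param scores Integer scores in `0..6`.
#' @return An ordered factor with levels `"0-2" < "3" < ... < "6"` (absent
#'   levels dropped).
#' @export
collapse_low_categories <- function(scores) {
  if (!all(is.na(scores) | (scores %in% 0:6))) {
    abort("Scores must lie in 0..6.")
  }
  lab <- ifelse(scores <= 2, "0-2", as.character(scores))
  factor(lab, levels = c("0-2", "3", "4", "5", "6"), ordered = TRUE,
         exclude = NULL) |> droplevels()
}

#' First-stage instrument-exposure regression
#'
#' Intercept-included least-squares fit of the exposure on the instrument
#' (plus optional exogenous covariates), summarizing instrument strength:
#' model R-squared, the overall regression F, and — when covariates are
#' present — the partial F for the instrument term. For the crude
#' single-regressor fit the identity `F = R^2 (n - 2) / (1 - R^2)` holds
#' exactly. An F at or below 10 flags a weak instrument.
#'
#' @param data Data frame holding all columns (complete cases).
#' @param exposure,instrument Column names.
#' @param covariates Optional character vector of covariate column names.
#' @return A `first_stage_fit` list: `slope`, `r_squared`, `f_statistic`,
#'   `partial_f`, `n`, `weak`.
#' @export
first_stage_fit <- function(data, exposure, instrument, covariates = NULL) {
  assert_columns(data, c(exposure, instrument, covariates))
  d <- complete_cases(data, c(exposure, instrument, covariates))
  y <- d[[exposure]]
  x <- design_matrix(d, c(instrument, covariates))
  if (nrow(d) <= ncol(x) + 1) abort("Too few observations for the first stage.")
  fit <- lsfit_basic(y, x)
  r2 <- fit$r_squared
  f_stat <- if (r2 >= 1 - 1e-14) Inf else
    (r2 / ncol(x)) / ((1 - r2) / fit$df_residual)
  partial_f <- NA_real_
  if (length(covariates)) {
    x0 <- design_matrix(d, covariates)
    fit0 <- lsfit_basic(y, x0)
    rss0 <- fit0$rss; rss1 <- fit$rss
    q <- ncol(x) - ncol(x0)
    partial_f <- ((rss0 - rss1) / q) / (rss1 / fit$df_residual)
  }
  structure(
    list(slope = unname(fit$coefficients[instrument]),
         r_squared = r2,
         f_statistic = f_stat,
         partial_f = partial_f,
         n = nrow(d),
         weak = f_stat <= 10),
    class = "first_stage_fit"
  )
}

#' @export
print.first_stage_fit <- function(x, ...) {
  cat(sprintf("First stage: slope %.4f, R^2 %.4f, F %.2f, n %d%s\n",
              x$slope, x$r_squared, x$f_statistic, x$n,
              if (x$weak) " [weak: F <= 10]" else ""))
  invisible(x)
}

#' Systematic search for the strongest allele-score instrument
#'
#' Enumerates every combination of `k` SNPs from the pooled candidate set
#' (combinations may come from a single gene), and for each combination:
#' orients the SNPs toward the trait-raising allele, builds the additive
#' score on that combination's complete-case sample, fits the crude
#' first-stage regression, and records its F. Returns the combination with
#' the largest first-stage F; ties break deterministically toward the
#' lexicographically smallest SNP-id set. The selection F is always from the
#' covariate-free first stage.
#'
#' Because orientation and selection use the analysis sample itself, the
#' winning F is subject to selection optimism; `split_sample = TRUE`
#' orients/selects on a random half and re-estimates the reported first
#' stage on the held-out half.
#'
#' @param data Data frame with the (transformed) exposure and candidate
#'   dosage columns.
#' @param exposure Exposure column name.
#' @param candidates Character vector of candidate SNP columns (>= k).
#' @param k Combination size (default 3; 4 supported).
#' @param split_sample Orient/select on a random half, estimate on the other.
#' @return An `instrument_search` list: `spec` (snp ids, orientation,
#'   score type), `fit` (the winning [first_stage_fit()]), `evaluated`
#'   (tibble of all combinations with F, R-squared, n), `weak`.
#' @export
search_best_instrument <- function(data, exposure, candidates, k = 3,
                                   split_sample = FALSE) {
  k <- assert_count(k, "k", min = 1)
  candidates <- sort(unique(candidates))
  if (length(candidates) < k) {
    abort(sprintf("Need at least k = %d candidate SNPs, got %d.",
                  k, length(candidates)))
  }
  assert_columns(data, c(exposure, candidates))
  select_data <- data
  estimate_data <- data
  if (split_sample) {
    half <- sample(c(TRUE, FALSE), nrow(data), replace = TRUE)
    select_data <- data[half, , drop = FALSE]
    estimate_data <- data[!half, , drop = FALSE]
  }
  combos <- combn(candidates, k, simplify = FALSE)
  eval_one <- function(snps, d) {
    cc <- complete_cases(d, c(exposure, snps))
    ori <- orient_risk_alleles(cc, exposure, snps)
    scored <- build_score(ori$data, snps, name = ".score")
    fit <- first_stage_fit(scored, exposure, ".score")
    list(fit = fit, orientation = ori$orientation)
  }
  # vectorized screening pass over all combinations: per-combination
  # complete cases, slope-sign orientation, score, crude F — plain matrix
  # arithmetic, identical to eval_one() on the winning combination
  y_all <- select_data[[exposure]]
  m_all <- as.matrix(select_data[, candidates, drop = FALSE])
  storage.mode(m_all) <- "double"
  ok_mat <- !is.na(m_all)
  ok_y <- !is.na(y_all)
  screened <- vapply(combos, function(snps) {
    ok <- ok_y
    for (s in snps) ok <- ok & ok_mat[, s]
    n_cc <- sum(ok)
    if (n_cc < 4) return(c(NA_real_, NA_real_, n_cc))
    y <- y_all[ok]
    yc <- y - mean(y)
    score <- numeric(n_cc)
    for (s in snps) {
      g <- m_all[ok, s]
      score <- score + if (sum(yc * g) < 0) 2 - g else g
    }
    r2 <- cor(y, score)^2
    c(r2 * (n_cc - 2) / (1 - r2), r2, n_cc)
  }, double(3))
  evaluated <- tibble::tibble(
    snp_ids = vapply(combos, paste, "", collapse = "+"),
    f_statistic = screened[1, ],
    r_squared = screened[2, ],
    n = as.integer(screened[3, ])
  )
  best_idx <- which.max(evaluated$f_statistic) # first max = lexicographic tie-break
  best_snps <- combos[[best_idx]]
  best <- eval_one(best_snps, estimate_data)
  structure(
    list(spec = list(snp_ids = best_snps,
                     orientation = best$orientation,
                     score_type = if (k == 1) "single_snp" else "additive_score"),
         fit = best$fit,
         evaluated = evaluated,
         weak = best$fit$weak,
         k = k, n_evaluated = length(combos)),
    class = "instrument_search"
  )
}

#' @export
print.instrument_search <- function(x, ...) {
  cat(sprintf("Best %d-SNP instrument over %d combinations: %s\n",
              x$k, x$n_evaluated, paste(x$spec$snp_ids, collapse = " + ")))
  print(x$fit)
  invisible(x)
}

#' Nonparametric test for trend across ordered groups
#'
#' Wilcoxon-type rank test for trend (Cuzick): ranks all observations
#' jointly, correlates the rank with the ordinal group score, and refers the
#' standardized statistic to the normal distribution. Mid-ranks are used for
#' ties, with the usual tie correction in the variance.
#'
#' @param values Numeric outcome values.
#' @param groups Ordinal group membership (ordered factor or numeric scores).
#' @return A tibble with `z`, `p_value` (two-sided) and `n`.
#' @export
trend_test <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  l <- if (is.numeric(groups)) groups else as.numeric(as.integer(factor(groups, ordered = TRUE)))
  if (length(unique(l)) < 2) abort("Need at least 2 ordered groups, each nonempty.")
  n <- length(values)
  r <- rank(values)
  t_stat <- sum(l * r)
  l_sum <- sum(l)
  e_t <- (n + 1) * l_sum / 2
  ties <- table(values)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  var_t <- (n * (n + 1) / 12) * (sum(l^2) - l_sum^2 / n) * tie_corr
  z <- (t_stat - e_t) / sqrt(var_t)
  tibble::tibble(z = z, p_value = 2 * pnorm(-abs(z)), n = n)
}

#' Instrument-confounder balance checks
#'
#' A valid instrument must be unrelated to confounders of the
#' exposure-outcome relation. For each supplied confounder this reports the
#' association with the instrument: a simple linear regression for
#' continuous confounders, and a chi-square test of independence across
#' instrument categories for binary/categorical ones. No automatic verdict
#' is rendered — small p-values are flags for the analyst.
#'
#' @param data Data frame holding the instrument and confounder columns.
#' @param instrument Instrument column name (dosage or score).
#' @param confounders Character vector of confounder column names (may be
#'   empty, yielding an empty report).
#' @return A tibble with one row per confounder: `confounder`, `type`,
#'   `estimate` (regression slope; `NA` for categorical), `p_value`, `n`.
#' @export
confounder_balance <- function(data, instrument, confounders) {
  if (length(confounders) == 0) {
    return(tibble::tibble(confounder = character(), type = character(),
                          estimate = double(), p_value = double(),
                          n = integer()))
  }
  assert_columns(data, c(instrument, confounders))
  purrr::map_dfr(confounders, function(cf) {
    d <- data[!is.na(data[[instrument]]) & !is.na(data[[cf]]), ]
    x <- d[[instrument]]; y <- d[[cf]]
    categorical <- is.factor(y) || is.character(y) ||
      (is.numeric(y) && length(unique(y)) <= 2)
    if (categorical) {
      tab <- table(factor(x), factor(y))
      p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      tibble::tibble(confounder = cf, type = "categorical",
                     estimate = NA_real_, p_value = p, n = nrow(d))
    } else {
      fit <- lsfit_basic(y, design_matrix(d, instrument))
      tt <- fit$coef_table[instrument, ]
      tibble::tibble(confounder = cf, type = "continuous",
                     estimate = tt[["estimate"]], p_value = tt[["p_value"]],
                     n = nrow(d))
    }
  })
}
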