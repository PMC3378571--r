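#' Define a panel of SNPs for simulation
#'
#' Describes the biallelic SNPs available to the simulator: their minor allele
#' frequency, genotyping call rate, and an inbreeding coefficient controlling
#' departure from Hardy-Weinberg proportions (0 = exact HWE; positive values
#' deplete heterozygotes, as a genotyping artifact would).
#'
#' @param snp_id Character vector of SNP identifiers.
#' @param gene Gene region label for each SNP; one of `"FTO"`, `"MC4R"`,
#'   `"TMEM18"` (adiposity candidates) or `"SLC2A9"` (urate candidates).
#' @param maf Minor allele frequency per SNP, in (0, 0.5].
#' @param call_rate Genotyping call rate per SNP, in (0, 1].
#' @param hwe_inbreeding Inbreeding coefficient per SNP (0 = HWE).
#'
#' @return A tibble with one row per SNP, columns `snp_id`, `gene`, `maf`,
#'   `call_rate`, `hwe_inbreeding`.
#' @export
#' @examples
#' snp_def("rs1", "FTO", maf = 0.4)
snp_def <- function(snp_id, gene, maf, call_rate = 1, hwe_inbreeding = 0) {
  gene <- match.arg(gene, c("FTO", "MC4R", "TMEM18", "SLC2A9"),
                    several.ok = TRUE)
  def <- tibble::tibble(
    snp_id = as.character(snp_id), gene = gene, maf = maf,
    call_rate = call_rate, hwe_inbreeding = hwe_inbreeding
  )
  validate_snp_def(def)
  def
}

validate_snp_def <- function(def) {
  assert_columns(def, c("snp_id", "gene", "maf", "call_rate", "hwe_inbreeding"),
                 "snps")
  if (anyDuplicated(def$snp_id)) abort("SNP ids must be distinct.")
  if (!all(def$maf > 0 & def$maf <= 0.5)) {
    abort("MAF must be > 0 and <= 0.5 for every SNP.")
  }
  if (!all(def$call_rate > 0 & def$call_rate <= 1)) {
    abort("call_rate must be in (0, 1] for every SNP.")
  }
  p <- def$maf; q <- 1 - p; f <- def$hwe_inbreeding
  if (any(p^2 + f * p * q < 0 | 2 * p * q * (1 - f) < 0 | q^2 + f * p * q < 0)) {
    abort("hwe_inbreeding yields negative genotype frequencies for some SNP.")
  }
  invisible(def)
}

#' Default SNP panel
#'
#' A panel of 24 candidate instruments spread over the four gene regions the
#' analysis draws on — ten adiposity candidates in and around FTO, four near
#' MC4R, six near TMEM18, and four urate candidates near SLC2A9, echoing the
#' relative sizes of the candidate sets such regions yield. MAFs span
#' 0.20-0.45; per-SNP call rates default to 0.98 so that a per-sample call
#' rate over a panel this small remains a meaningful QC quantity.
#'
#' @param call_rate Genotyping call rate shared by all SNPs in the panel.
#' @return A SNP definition tibble (see [snp_def()]).
#' @export
snp_panel <- function(call_rate = 0.98) {
  genes <- rep(c("FTO", "MC4R", "TMEM18", "SLC2A9"), times = c(10, 4, 6, 4))
  ids <- unlist(lapply(c(FTO = 10, MC4R = 4, TMEM18 = 6, SLC2A9 = 4),
                       function(k) letters[seq_len(k)]))
  ids <- paste0(tolower(genes), "_", ids)
  mafs <- rep(c(0.40, 0.30, 0.22, 0.35, 0.25, 0.28, 0.45, 0.20), length.out = 24)
  snp_def(snp_id = ids, gene = genes, maf = mafs, call_rate = call_rate)
}

#' True generative parameters for a simulated cohort
#'
#' Fixes the causal structure the simulator embeds: the direction(s) of the
#' causal arrow between latent adiposity and latent serum uric acid (SUA),
#' the standardized causal effect, the loadings of a shared latent confounder
#' on each trait, and the population variance each genetic instrument explains
#' in its own trait.
#'
#' Defaults reflect the study conditions the package validates against: an
#' adiposity-to-SUA effect of 0.30 SD/SD, confounder loadings of 0.45 on both
#' traits, a urate SNP explaining 3.16% of SUA variance and a three-SNP
#' adiposity score explaining 0.60% of latent adiposity variance.
#'
#' @param direction One of `"adiposity_to_sua"`, `"sua_to_adiposity"`,
#'   `"null"`, `"both"`.
#' @param beta_causal Standardized causal effect (per SD) applied along each
#'   active direction.
#' @param conf_exposure,conf_outcome Loadings of the shared confounder U on
#'   latent adiposity and latent SUA respectively.
#' @param r2_sua_instrument Population variance in SUA explained by the
#'   SLC2A9-like SNP, in \[0, 1).
#' @param r2_adip_instrument Population variance in latent adiposity explained
#'   by the additive allele score, in \[0, 1).
#'
#' @return A list of class `mr_true_params`.
#' @export
true_params <- function(direction = c("adiposity_to_sua", "sua_to_adiposity",
                                      "null", "both"),
                        beta_causal = 0.30,
                        conf_exposure = 0.45,
                        conf_outcome = 0.45,
                        r2_sua_instrument = 0.0316,
                        r2_adip_instrument = 0.0060) {
  direction <- match.arg(direction)
  assert_fraction(r2_sua_instrument, "r2_sua_instrument", lo_open = FALSE)
  assert_fraction(r2_adip_instrument, "r2_adip_instrument", lo_open = FALSE)
  structure(
    list(direction = direction, beta_causal = beta_causal,
         conf_exposure = conf_exposure, conf_outcome = conf_outcome,
         r2_sua_instrument = r2_sua_instrument,
         r2_adip_instrument = r2_adip_instrument),
    class = "mr_true_params"
  )
}

#' Scenario configuration for cohort simulation
#'
#' Bundles everything [simulate_cohort()] needs: sample size, SNP panel, the
#' true generative parameters, which SNPs are causal, phenotype missingness
#' and whether traits are emitted on the raw measurement scale (kg, cm,
#' umol/L) or as standardized latent values.
#'
#' @param n_samples Number of participants (>= 10).
#' @param snps SNP definition tibble (see [snp_def()], [snp_panel()]).
#' @param params True generative parameters (see [true_params()]).
#' @param score_snps SNP ids forming the causal adiposity allele score.
#'   Default: the first adiposity SNP of each of FTO, MC4R and TMEM18.
#' @param sua_snp SNP id of the causal urate variant. Default: the first
#'   SLC2A9 SNP in the panel.
#' @param trait_loadings Named loadings of the four measured adiposity traits
#'   on latent adiposity (each in (0, 1]).
#' @param missing_rate_pheno Fraction of phenotype entries set missing,
#'   independently per trait (MCAR).
#' @param bad_sample_rate Fraction of samples with degraded DNA whose
#'   genotypes are additionally missing at rate `1 - bad_sample_call` — the
#'   kind of sample the per-sample call-rate QC filter exists to remove.
#' @param bad_sample_call Call rate within degraded samples.
#' @param raw_scale If `TRUE` (default), traits are mapped to raw units by
#'   inverting the analysis transformations (exp for weight/waist, square for
#'   SUA/fat mass, inverse square for BMI) around fixed sex-specific
#'   location/scale constants; if `FALSE`, standardized latent traits are
#'   emitted directly.
#' @param seed Integer seed; a fixed seed makes the cohort byte-identical
#'   across calls.
#'
#' @return A list of class `mr_scenario`.
#' @export
scenario_config <- function(n_samples = 6184,
                            snps = snp_panel(),
                            params = true_params(),
                            score_snps = NULL,
                            sua_snp = NULL,
                            trait_loadings = c(weight = 0.98, waist = 0.96,
                                               bmi = 0.95, fat_mass = 0.93),
                            missing_rate_pheno = 0.005,
                            bad_sample_rate = 0.01,
                            bad_sample_call = 0.5,
                            raw_scale = TRUE,
                            seed = 1L) {
  n_samples <- assert_count(n_samples, "n_samples", min = 10)
  validate_snp_def(snps)
  if (!inherits(params, "mr_true_params")) abort("`params` must come from true_params().")
  assert_fraction(missing_rate_pheno, "missing_rate_pheno",
                  lo_open = FALSE, hi_open = TRUE)
  adip <- snps$snp_id[snps$gene != "SLC2A9"]
  urate <- snps$snp_id[snps$gene == "SLC2A9"]
  if (is.null(score_snps)) {
    first_of <- function(g) {
      ids <- snps$snp_id[snps$gene == g]
      if (length(ids)) ids[1] else NULL
    }
    score_snps <- unlist(lapply(c("FTO", "MC4R", "TMEM18"), first_of))
    if (length(score_snps) == 0) score_snps <- utils::head(adip, 3)
  }
  if (is.null(sua_snp)) sua_snp <- urate[1]
  if (length(sua_snp) != 1 || !sua_snp %in% snps$snp_id) {
    abort("`sua_snp` must name one SNP in the panel.")
  }
  if (!all(score_snps %in% snps$snp_id) || length(score_snps) < 1) {
    abort("`score_snps` must name SNPs in the panel.")
  }
  traits <- c("weight", "waist", "bmi", "fat_mass")
  if (!all(traits %in% names(trait_loadings)) ||
      !all(trait_loadings > 0 & trait_loadings <= 1)) {
    abort("`trait_loadings` must name weight, waist, bmi, fat_mass with values in (0, 1].")
  }
  structure(
    list(n_samples = n_samples, snps = snps, params = params,
         score_snps = score_snps, sua_snp = sua_snp,
         trait_loadings = trait_loadings[traits],
         missing_rate_pheno = missing_rate_pheno,
         bad_sample_rate = bad_sample_rate,
         bad_sample_call = bad_sample_call,
         raw_scale = isTRUE(raw_scale), seed = as.integer(seed)),
    class = "mr_scenario"
  )
}

#' Simulate biallelic genotypes under (possibly perturbed) Hardy-Weinberg
#'
#' Draws diploid dosages (count of the minor/alternate allele, 0/1/2) for
#' each SNP from the Hardy-Weinberg trinomial at its MAF, adjusted by the
#' SNP's inbreeding coefficient `f`: P(2) = p^2 + f p q, P(1) = 2 p q (1 - f),
#' P(0) = q^2 + f p q. Entries are set missing uniformly at random at rate
#' 1 - call_rate.
#'
#' @param n Number of samples.
#' @param snps SNP definition tibble (see [snp_def()]).
#' @param seed Optional integer seed (local to this call).
#' @return An integer matrix (n x number of SNPs, colnames = snp ids) with
#'   values 0/1/2 and `NA` for missing calls.
#' @export
#' @examples
#' g <- simulate_genotypes(100, snp_def("rs1", "FTO", 0.3), seed = 1)
#' table(g)
simulate_genotypes <- function(n, snps, seed = NULL) {
  n <- assert_count(n, "n", min = 1)
  validate_snp_def(snps)
  draw <- function() {
    m <- nrow(snps)
    out <- matrix(NA_integer_, n, m, dimnames = list(NULL, snps$snp_id))
    for (j in seq_len(m)) {
      p <- snps$maf[j]; q <- 1 - p; f <- snps$hwe_inbreeding[j]
      probs <- c(q^2 + f * p * q, 2 * p * q * (1 - f), p^2 + f * p * q)
      g <- sample.int(3L, n, replace = TRUE, prob = probs) - 1L
      cr <- snps$call_rate[j]
      if (cr < 1) g[runif(n) >= cr] <- NA_integer_
      out[, j] <- g
    }
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Calibrate a genetic effect to a target variance explained
#'
#' Returns the coefficient `a = sqrt(target_r2 / regressor_variance)` such
#' that a unit-variance trait built as `a * G + noise` (noise variance
#' `1 - target_r2`) has population R-squared equal to `target_r2` when
#' regressed on `G`.
#'
#' @param target_r2 Target variance explained, in \[0, 1).
#' @param regressor_variance Population variance of the regressor (e.g.
#'   `2 p (1 - p)` for a HWE SNP, or the sum over score SNPs).
#' @return The calibrated coefficient (non-negative scalar).
#' @export
#' @examples
#' calibrate_effect(0.0316, 2 * 0.5 * 0.5) # SNP at MAF 0.5
calibrate_effect <- function(target_r2, regressor_variance) {
  assert_fraction(target_r2, "target_r2", lo_open = FALSE)
  if (!is.numeric(regressor_variance) || length(regressor_variance) != 1 ||
      !is.finite(regressor_variance) || regressor_variance <= 0) {
    abort("`regressor_variance` must be a positive scalar.")
  }
  sqrt(target_r2 / regressor_variance)
}

# Residual variances making both latent traits unit-variance under the
# simultaneous system A = b_sa S + x_A, S = b_as A + x_S. Linear 2x2 solve;
# negative solutions mean the variance budget is overspent.
latent_residual_vars <- function(params, r2_adip, r2_sua) {
  b_as <- if (params$direction %in% c("adiposity_to_sua", "both")) params$beta_causal else 0
  b_sa <- if (params$direction %in% c("sua_to_adiposity", "both")) params$beta_causal else 0
  c_a <- params$conf_exposure; c_s <- params$conf_outcome
  d <- 1 - b_as * b_sa
  if (abs(d) < 1e-8) abort("Feedback loop beta^2 = 1: system is degenerate.")
  ha <- r2_adip + c_a^2            # non-residual variance of the A shock
  hs <- r2_sua + c_s^2
  cc <- c_a * c_s                  # shock covariance via shared U
  rhs <- c(d^2 - ha - b_sa^2 * hs - 2 * b_sa * cc,
           d^2 - hs - b_as^2 * ha - 2 * b_as * cc)
  m <- matrix(c(1, b_as^2, b_sa^2, 1), 2, 2)
  v <- solve(m, rhs)
  if (v[1] <= 0) abort("Variance budget exceeded for trait `adiposity`: residual variance <= 0.")
  if (v[2] <= 0) abort("Variance budget exceeded for trait `sua`: residual variance <= 0.")
  list(v_a = v[1], v_s = v[2], b_as = b_as, b_sa = b_sa, d = d)
}

#' Population regression slopes implied by the generative model
#'
#' Covariance algebra for the simulator's structural equations: the slopes
#' that OLS and (two-stage least squares via the genetic instruments)
#' converge to in large samples, for both analysis directions. Used to
#' predict confounding bias in parameter-recovery checks.
#'
#' @param params True generative parameters (see [true_params()]).
#' @param loading Loading of the measured adiposity trait on latent adiposity.
#' @return A tibble with columns `direction`, `method`, `slope`: the
#'   large-sample OLS and IV slopes of SUA on the trait
#'   (`adiposity_to_sua` rows) and of the trait on SUA (`sua_to_adiposity`).
#' @export
expected_slopes <- function(params, loading = 1) {
  vv <- latent_residual_vars(params, params$r2_adip_instrument,
                             params$r2_sua_instrument)
  c_a <- params$conf_exposure; c_s <- params$conf_outcome
  var_xa <- params$r2_adip_instrument + c_a^2 + vv$v_a
  var_xs <- params$r2_sua_instrument + c_s^2 + vv$v_s
  cov_x <- c_a * c_s
  # Cov(A, S) from A = (x_A + b_sa x_S)/d, S = (x_S + b_as x_A)/d
  cov_as <- (cov_x * (1 + vv$b_as * vv$b_sa) + vv$b_as * var_xa +
               vv$b_sa * var_xs) / vv$d^2
  tibble::tibble(
    direction = rep(c("adiposity_to_sua", "sua_to_adiposity"), each = 2),
    method = rep(c("OLS", "2SLS"), 2),
    slope = c(loading * cov_as,            # SUA ~ trait, confounded
              vv$b_as / loading,           # SUA ~ trait, score-instrumented
              loading * cov_as,            # trait ~ SUA, confounded
              loading * vv$b_sa)           # trait ~ SUA, SNP-instrumented
  )
}

# raw-scale back-transform constants, per trait and sex, on the transformed
# scale: raw = inverse_transform(location + scale * z). Fixed plumbing chosen
# to give means/SDs typical of a middle-aged European cohort.
raw_scale_map <- list(
  weight   = list(loc = c(men = 4.39, women = 4.19), scale = 0.18,
                  inv = function(t) exp(t)),
  waist    = list(loc = c(men = 4.56, women = 4.42), scale = 0.13,
                  inv = function(t) exp(t)),
  bmi      = list(loc = c(men = -0.1939, women = -0.1996), scale = 0.0165,
                  inv = function(t) 1 / pmin(t, -0.05)^2),
  fat_mass = list(loc = c(men = 4.45, women = 4.84), scale = 0.85,
                  inv = function(t) pmax(t, 0.5)^2),
  sua      = list(loc = c(men = 19.0, women = 16.45), scale = 2.0,
                  inv = function(t) pmax(t, 1)^2)
)

#' Simulate a genotype-phenotype cohort
#'
#' Generates a cohort with the statistical structure a bidirectional
#' Mendelian-randomization analysis assumes. Latent standardized adiposity A
#' and serum uric acid S follow structural equations with a shared standard
#' normal confounder U:
#'
#'   A = b_sa S + a_A score_c + c_A U + e_A,
#'   S = b_as A + a_S g_c + c_S U + e_S,
#'
#' where `score_c` is the centered causal allele score, `g_c` the centered
#' urate SNP dosage, the genetic coefficients are calibrated so the score and
#' SNP explain exactly the configured variance fractions, the causal
#' coefficients `b_as`/`b_sa` are switched on by the configured direction,
#' and the residual variances are solved so both latents have population
#' variance 1. The four measured adiposity traits load on A with the
#' configured trait loadings; covariates (age, sex, smoking, alcohol,
#' diuretic use, creatinine) are noisy functions of U, so that covariate
#' adjustment removes only part of the confounding.
#'
#' @param config Scenario configuration (see [scenario_config()]).
#' @return An `mr_cohort`: a list with tibbles `phenotypes` (one row per
#'   sample: id, covariates, traits) and `genotypes` (id + one dosage column
#'   per SNP), the `snp_info` panel, and the generating `config`.
#' @export
#' @examples
#' coh <- simulate_cohort(scenario_config(n_samples = 200, seed = 7))
#' coh
simulate_cohort <- function(config) {
  if (!inherits(config, "mr_scenario")) abort("`config` must come from scenario_config().")
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- config$n_samples
  snps <- config$snps
  p <- config$params

  # causal genetic regressors use the complete (pre-missingness) dosages so
  # the generative model is well-defined; analysis sees the masked version
  geno_full <- simulate_genotypes(n, dplyr::mutate(snps, call_rate = 1))
  geno <- geno_full
  for (j in seq_len(ncol(geno))) {
    cr <- snps$call_rate[j]
    if (cr < 1) geno[runif(n) >= cr, j] <- NA_integer_
  }
  # degraded-DNA samples: heavy genotype missingness across the whole panel
  bad <- runif(n) < config$bad_sample_rate
  if (any(bad)) {
    drop_mask <- matrix(runif(sum(bad) * ncol(geno)) >= config$bad_sample_call,
                        nrow = sum(bad))
    geno[bad, ][drop_mask] <- NA_integer_
  }

  maf_of <- setNames(snps$maf, snps$snp_id)
  score_var <- sum(2 * maf_of[config$score_snps] * (1 - maf_of[config$score_snps]))
  g_var <- 2 * maf_of[config$sua_snp] * (1 - maf_of[config$sua_snp])
  a_adip <- calibrate_effect(p$r2_adip_instrument, score_var)
  a_sua <- calibrate_effect(p$r2_sua_instrument, g_var)

  score_c <- rowSums(geno_full[, config$score_snps, drop = FALSE]) -
    sum(2 * maf_of[config$score_snps])
  g_c <- geno_full[, config$sua_snp] - 2 * maf_of[config$sua_snp]

  vv <- latent_residual_vars(p, p$r2_adip_instrument, p$r2_sua_instrument)
  u <- rnorm(n)
  x_a <- a_adip * score_c + p$conf_exposure * u + rnorm(n, sd = sqrt(vv$v_a))
  x_s <- a_sua * g_c + p$conf_outcome * u + rnorm(n, sd = sqrt(vv$v_s))
  lat_a <- (x_a + vv$b_sa * x_s) / vv$d
  lat_s <- (x_s + vv$b_as * x_a) / vv$d

  lam <- config$trait_loadings
  traits <- tibble::tibble(
    weight   = lam["weight"] * lat_a + sqrt(1 - lam["weight"]^2) * rnorm(n),
    bmi      = lam["bmi"] * lat_a + sqrt(1 - lam["bmi"]^2) * rnorm(n),
    waist    = lam["waist"] * lat_a + sqrt(1 - lam["waist"]^2) * rnorm(n),
    fat_mass = lam["fat_mass"] * lat_a + sqrt(1 - lam["fat_mass"]^2) * rnorm(n),
    sua      = lat_s
  )

  sex <- factor(ifelse(runif(n) < 0.474, "men", "women"),
                levels = c("men", "women"))
  age <- round(53.1 + 10.7 * (0.30 * u + sqrt(1 - 0.30^2) * rnorm(n)), 1)
  age <- pmin(pmax(age, 35), 75)
  smoking <- rbinom(n, 1, stats::plogis(-0.95 + 0.50 * u))
  alcohol <- rbinom(n, 1, stats::plogis(-1.85 + 0.40 * u +
                                          1.05 * (sex == "men")))
  diuretic <- rbinom(n, 1, stats::plogis(-3.8 + 0.30 * u))
  creatinine <- round(ifelse(sex == "men", 88, 72) +
                        12 * (0.25 * u + sqrt(1 - 0.25^2) * rnorm(n)), 1)
  creatinine <- pmax(creatinine, 30)

  if (config$raw_scale) {
    for (tr in names(raw_scale_map)) {
      mp <- raw_scale_map[[tr]]
      t_scale <- mp$loc[as.character(sex)] + mp$scale * traits[[tr]]
      traits[[tr]] <- round(mp$inv(unname(t_scale)), 2)
    }
  }

  if (config$missing_rate_pheno > 0) {
    for (tr in c(names(raw_scale_map))) {
      traits[[tr]][runif(n) < config$missing_rate_pheno] <- NA_real_
    }
  }

  ids <- sprintf("S%05d", seq_len(n))
  phenotypes <- tibble::tibble(
    sample_id = ids, sex = sex, age = age,
    smoking = smoking, alcohol = alcohol, diuretic = diuretic,
    creatinine = creatinine
  )
  phenotypes <- dplyr::bind_cols(phenotypes, traits)

  genotypes <- tibble::as_tibble(geno)
  genotypes <- dplyr::bind_cols(tibble::tibble(sample_id = ids), genotypes)

  new_mr_cohort(phenotypes, genotypes, snps, config)
}

#' Monte-Carlo distribution of the first-stage F statistic
#'
#' Repeatedly simulates a cohort-scale first stage — HWE genotypes for the
#' given MAFs, an additive allele score over them, and an exposure built so
#' the score explains exactly `target_r2` of its population variance — and
#' records the crude first-stage F of each replicate. With a single MAF this
#' is the single-SNP instrument case.
#'
#' @param n Analysis sample size per replicate.
#' @param target_r2 Population variance explained by the instrument.
#' @param mafs MAF per score SNP (length 1 for a single-SNP instrument).
#' @param reps Number of replicates.
#' @param seed Integer seed.
#' @return Numeric vector of `reps` F statistics.
#' @export
simulate_first_stage_f <- function(n, target_r2, mafs, reps = 300, seed = 1) {
  snps <- snp_def(paste0("s", seq_along(mafs)),
                  rep("FTO", length(mafs)), maf = mafs)
  score_var <- sum(2 * mafs * (1 - mafs))
  a <- calibrate_effect(target_r2, score_var)
  withr::with_seed(as.integer(seed), {
    vapply(seq_len(reps), function(i) {
      g <- simulate_genotypes(n, snps)
      d <- tibble::tibble(score = as.integer(rowSums(g)))
      d$exposure <- a * d$score + rnorm(n, sd = sqrt(1 - target_r2))
      first_stage_fit(d, "exposure", "score")$f_statistic
    }, double(1))
  })
}
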