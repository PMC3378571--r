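# Small simulated instrumental-variable dataset: one HWE SNP instrument,
# exposure x confounded with outcome y through u, causal effect `beta`.
make_iv_data <- function(n, beta = 0.3, conf = 0.5, r2 = 0.03, maf = 0.3,
                         seed = 1) {
  withr::with_seed(seed, {
    z <- rbinom(n, 2, maf)
    u <- rnorm(n)
    a <- sqrt(r2 / (2 * maf * (1 - maf)))
    x <- a * (z - 2 * maf) + conf * u + rnorm(n, sd = sqrt(1 - r2 - conf^2))
    # outcome noise scaled so Var(y) = 1 (cov(x, u) = conf)
    v_y <- 1 - beta^2 - conf^2 - 2 * beta * conf^2
    y <- beta * x + conf * u + rnorm(n, sd = sqrt(max(v_y, 0.1)))
    tibble::tibble(z = z, x = x, y = y, u = u)
  })
}

# tiny deterministic cohort for container/IO tests
make_toy_cohort <- function(n = 40, seed = 11) {
  simulate_cohort(scenario_config(
    n_samples = n,
    snps = snp_def(c("s1", "s2", "s3", "g1"),
                   c("FTO", "MC4R", "TMEM18", "SLC2A9"),
                   maf = c(0.3, 0.25, 0.4, 0.3),
                   call_rate = c(1, 1, 0.9, 1)),
    missing_rate_pheno = 0.02,
    seed = seed
  ))
}

# fast standardized-scale scenario used by recovery simulations: complete
# genotypes and phenotypes so the analysis sample equals n_samples
recovery_config <- function(n = 5000, direction = "adiposity_to_sua",
                            beta = 0.30, conf = 0.45,
                            r2_adip = 0.006, r2_sua = 0.0316, seed = 1) {
  scenario_config(
    n_samples = n,
    snps = snp_panel(call_rate = 1),
    params = true_params(direction = direction, beta_causal = beta,
                         conf_exposure = conf, conf_outcome = conf,
                         r2_sua_instrument = r2_sua,
                         r2_adip_instrument = r2_adip),
    missing_rate_pheno = 0,
    bad_sample_rate = 0,
    raw_scale = FALSE,
    seed = seed
  )
}

# joined analysis frame with allele score and standardized traits, using the
# generator's known causal SNPs (no instrument search)
recovery_frame <- function(cohort) {
  cfg <- cohort$config
  d <- dplyr::left_join(cohort$phenotypes, cohort$genotypes, by = "sample_id")
  d <- build_score(d, cfg$score_snps)
  d$sua_z <- standardize(d$sua)
  d$weight_z <- standardize(d$weight)
  d
}
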