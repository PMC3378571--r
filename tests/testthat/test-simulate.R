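test_that("genotype frequencies follow HWE, adjusted by inbreeding", {
  n <- 1e5
  g <- simulate_genotypes(n, snp_def("s", "FTO", maf = 0.5), seed = 101)
  freqs <- tabulate(g + 1L, 3) / n
  for (i in 1:3) {
    expected <- c(0.25, 0.5, 0.25)[i]
    tol <- 3 * sqrt(expected * (1 - expected) / n)
    expect_lt(abs(freqs[i] - expected), tol)
  }
  expect_lt(abs(mean(g) - 1), 3 * sqrt(0.5 / n))

  # heterozygote depletion under positive inbreeding: 2*0.2*0.8*(1-0.5)=0.16
  g2 <- simulate_genotypes(n, snp_def("s", "FTO", maf = 0.2,
                                      hwe_inbreeding = 0.5), seed = 102)
  het <- mean(g2 == 1)
  expect_lt(abs(het - 0.16), 4 * sqrt(0.16 * 0.84 / n))
})

test_that("every panel SNP stays within 4 SD of its HWE expectation", {
  n <- 1e5
  panel <- snp_panel(call_rate = 1)
  g <- simulate_genotypes(n, panel, seed = 103)
  for (j in seq_len(nrow(panel))) {
    p <- panel$maf[j]
    expected <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- tabulate(g[, j] + 1L, 3) / n
    tol <- 4 * sqrt(expected * (1 - expected) / n)
    expect_true(all(abs(obs - expected) < tol))
  }
})

test_that("invalid SNP definitions and missingness are rejected", {
  expect_error(snp_def("s", "FTO", maf = 0), "MAF")
  expect_error(snp_def("s", "FTO", maf = 0.6), "MAF")
  expect_error(snp_def("s", "FTO", maf = 0.3, call_rate = 0), "call_rate")
  g <- simulate_genotypes(1000, snp_def("s", "FTO", 0.3, call_rate = 0.8),
                          seed = 1)
  expect_gt(mean(is.na(g)), 0.15)
  expect_lt(mean(is.na(g)), 0.25)
})

test_that("calibrate_effect hits its target variance explained", {
  expect_identical(calibrate_effect(0, 0.42), 0)
  expect_equal(calibrate_effect(0.0316, 0.5), sqrt(0.0316 / 0.5))
  expect_equal(round(calibrate_effect(0.0316, 0.5), 4), 0.2514)
  expect_error(calibrate_effect(1, 0.5), "target_r2")
  expect_error(calibrate_effect(0.1, 0), "regressor_variance")

  # Monte-Carlo round trip at large n: sample R^2 within +/- 0.002 of target
  withr::with_seed(7, {
    n <- 2e5
    maf <- 0.3
    g <- rbinom(n, 2, maf)
    a <- calibrate_effect(0.0316, 2 * maf * (1 - maf))
    trait <- a * g + rnorm(n, sd = sqrt(1 - 0.0316))
    r2 <- cor(trait, g)^2
    expect_lt(abs(r2 - 0.0316), 0.002)
  })
})

test_that("cohort simulation is deterministic given its seed", {
  cfg <- scenario_config(n_samples = 120, seed = 31)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$phenotypes, c2$phenotypes)
  expect_identical(c1$genotypes, c2$genotypes)
  c3 <- simulate_cohort(scenario_config(n_samples = 120, seed = 32))
  expect_false(identical(c1$phenotypes, c3$phenotypes))
})

test_that("latent traits have unit population variance by construction", {
  cfg <- recovery_config(n = 5e4, seed = 5)
  coh <- simulate_cohort(cfg)
  for (tr in c("weight", "bmi", "waist", "fat_mass", "sua")) {
    expect_lt(abs(sd(coh$phenotypes[[tr]]) - 1), 0.02)
  }
})

test_that("variance budget violations are rejected with the trait named", {
  expect_error(
    simulate_cohort(scenario_config(
      params = true_params(beta_causal = 0.9, conf_exposure = 0.45,
                           conf_outcome = 0.45))),
    "sua"
  )
  expect_error(
    simulate_cohort(scenario_config(
      params = true_params(conf_exposure = 1.2))),
    "adiposity"
  )
})

test_that("null scenario decouples the score from the outcome", {
  cfg <- recovery_config(n = 4000, direction = "null", beta = 0)
  est <- vapply(1:200, function(i) {
    cfg$seed <- i
    d <- recovery_frame(simulate_cohort(cfg))
    wald_ratio(d, "sua_z", "weight_z", "score")
  }, double(1))
  expect_lt(abs(mean(est)), 0.03)
})

test_that("expected_slopes matches hand algebra in the recursive case", {
  p <- true_params(direction = "adiposity_to_sua", beta_causal = 0.3,
                   conf_exposure = 0.45, conf_outcome = 0.45)
  es <- expected_slopes(p, loading = 0.98)
  ols <- es$slope[es$direction == "adiposity_to_sua" & es$method == "OLS"]
  iv <- es$slope[es$direction == "adiposity_to_sua" & es$method == "2SLS"]
  expect_equal(ols, 0.98 * (0.3 + 0.45^2))
  expect_equal(iv, 0.3 / 0.98)
  iv_rev <- es$slope[es$direction == "sua_to_adiposity" & es$method == "2SLS"]
  expect_equal(iv_rev, 0)
})

test_that("bidirectional feedback keeps both traits unit-variance", {
  cfg <- scenario_config(
    n_samples = 5e4,
    snps = snp_panel(call_rate = 1),
    params = true_params(direction = "both", beta_causal = 0.2),
    missing_rate_pheno = 0, raw_scale = FALSE, seed = 77
  )
  coh <- simulate_cohort(cfg)
  expect_lt(abs(sd(coh$phenotypes$sua) - 1), 0.02)
  expect_lt(abs(sd(coh$phenotypes$weight) - 1), 0.02)
})
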