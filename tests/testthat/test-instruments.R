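test_that("risk-allele orientation flips negative-slope SNPs and is idempotent", {
  withr::with_seed(2, {
    d <- tibble::tibble(g1 = rbinom(500, 2, 0.3), g2 = rbinom(500, 2, 0.4))
    d$y <- 0.3 * d$g1 - 0.3 * d$g2 + rnorm(500)
  })
  o1 <- orient_risk_alleles(d, "y", c("g1", "g2"))
  expect_identical(o1$orientation$flipped, c(FALSE, TRUE))
  expect_true(all(o1$orientation$slope > 0))
  # flipping negates the slope exactly
  raw_slope <- cov(d$y, d$g2) / var(d$g2)
  expect_equal(o1$orientation$slope[2], -raw_slope)
  # orienting twice equals orienting once
  o2 <- orient_risk_alleles(o1$data, "y", c("g1", "g2"))
  expect_identical(o2$data, o1$data)
  expect_error(orient_risk_alleles(dplyr::mutate(d, g3 = 1L), "y", "g3"),
               "monomorphic")
})

test_that("the additive allele score is a bounded integer sum", {
  d <- tibble::tibble(a = c(2L, 0L, 0L), b = c(2L, 0L, 1L), c = c(2L, 0L, 2L))
  s <- build_score(d, c("a", "b", "c"))$score
  expect_identical(s, c(6L, 0L, 3L))
  expect_error(build_score(tibble::tibble(a = NA_integer_), "a"), "Missing")
  expect_error(build_score(tibble::tibble(a = 3), "a"), "0, 1 or 2")
  # enumerating all triples of {0,1,2} dosages gives exactly 7 categories
  grid <- expand.grid(a = 0:2, b = 0:2, c = 0:2)
  all_scores <- build_score(grid, c("a", "b", "c"))$score
  expect_identical(sort(unique(all_scores)), 0:6)
})

test_that("sparse low score categories collapse into one ordered level", {
  lev <- collapse_low_categories(c(0L, 1L, 2L, 3L, 6L))
  expect_identical(as.character(lev), c("0-2", "0-2", "0-2", "3", "6"))
  expect_true(is.ordered(lev))
  expect_true(all(lev[1:3] < lev[4]) && lev[4] < lev[5])
  high <- collapse_low_categories(c(3L, 4L, 5L))
  expect_identical(nlevels(high), 3L)
  expect_error(collapse_low_categories(7L), "0..6")
})

test_that("first-stage F satisfies the R^2 identity", {
  # frozen arithmetic case: R^2 = 0.5 at n = 102 gives F = 100
  expect_equal(0.5 * (102 - 2) / (1 - 0.5), 100)
  withr::with_seed(33, {
    for (i in 1:10) {
      n <- 102
      d <- tibble::tibble(g = rbinom(n, 2, 0.3))
      d$x <- 0.2 * d$g + rnorm(n)
      fs <- first_stage_fit(d, "x", "g")
      expect_equal(fs$f_statistic,
                   fs$r_squared * (n - 2) / (1 - fs$r_squared),
                   tolerance = 1e-10)
      expect_identical(fs$n, 102L)
    }
  })
})

test_that("first stage reports the partial F for the instrument block", {
  withr::with_seed(34, {
    n <- 400
    d <- tibble::tibble(g = rbinom(n, 2, 0.3), age = rnorm(n))
    d$x <- 0.2 * d$g + 0.5 * d$age + rnorm(n)
  })
  fs <- first_stage_fit(d, "x", "g", covariates = "age")
  full <- lm(x ~ g + age, data = d)
  red <- lm(x ~ age, data = d)
  expect_equal(fs$partial_f, anova(red, full)$F[2], tolerance = 1e-10)
  expect_equal(fs$r_squared, summary(full)$r.squared, tolerance = 1e-10)
})

test_that("instrument search equals brute-force enumeration", {
  brute_force <- function(d, exposure, candidates, k) {
    combos <- combn(sort(candidates), k, simplify = FALSE)
    fs <- vapply(combos, function(snps) {
      cc <- d[complete.cases(d[, c(exposure, snps)]), ]
      sc <- 0
      for (s in snps) {
        slope <- cov(cc[[exposure]], cc[[s]]) / var(cc[[s]])
        sc <- sc + if (slope < 0) 2 - cc[[s]] else cc[[s]]
      }
      r2 <- cor(cc[[exposure]], sc)^2
      r2 * (nrow(cc) - 2) / (1 - r2)
    }, double(1))
    list(best = combos[[which.max(fs)]], f = max(fs), n_eval = length(combos))
  }
  withr::with_seed(44, {
    for (rep_i in 1:8) {
      m <- sample(3:7, 1); k <- sample(1:min(3, m), 1); n <- 300
      d <- tibble::as_tibble(
        setNames(lapply(1:m, function(i) rbinom(n, 2, runif(1, 0.2, 0.45))),
                 paste0("snp", letters[1:m]))
      )
      d$x <- rowSums(d[, 1:min(2, m)]) * 0.1 + rnorm(n)
      cands <- names(d)[1:m]
      res <- search_best_instrument(d, "x", cands, k = k)
      oracle <- brute_force(d, "x", cands, k)
      expect_identical(res$n_evaluated, oracle$n_eval)
      expect_identical(sort(res$spec$snp_ids), sort(oracle$best))
      expect_equal(res$fit$f_statistic, oracle$f, tolerance = 1e-8)
    }
  })
  expect_error(search_best_instrument(d, "x", cands[1:2], k = 3), "at least")
})

test_that("null SNPs give a weak-instrument flag", {
  withr::with_seed(55, {
    n <- 1000
    d <- tibble::tibble(a = rbinom(n, 2, 0.3), b = rbinom(n, 2, 0.3),
                        c = rbinom(n, 2, 0.3), d = rbinom(n, 2, 0.3),
                        x = rnorm(n))
  })
  res <- search_best_instrument(d, "x", c("a", "b", "c", "d"), k = 3)
  expect_identical(res$n_evaluated, 4L)
  expect_true(res$weak)
  expect_lt(res$fit$f_statistic, 10)
})

test_that("trend test is antisymmetric and detects monotone shifts", {
  withr::with_seed(66, {
    groups <- rep(0:4, each = 60)
    flat <- rnorm(300)
    shifted <- rnorm(300, mean = groups)
  })
  t_up <- trend_test(shifted, groups)
  expect_lt(t_up$p_value, 1e-3)
  expect_gt(t_up$z, 0)
  t_down <- trend_test(shifted, max(groups) - groups)
  expect_equal(t_down$z, -t_up$z, tolerance = 1e-12)
  expect_equal(t_down$p_value, t_up$p_value, tolerance = 1e-12)
  expect_error(trend_test(flat, rep(1, 300)), "2 ordered groups")
  # ordered-factor input matches numeric coding
  expect_equal(trend_test(shifted, factor(groups, ordered = TRUE))$z, t_up$z)
})

test_that("confounder balance flags built-in associations and nothing else", {
  withr::with_seed(77, {
    n <- 2000
    d <- tibble::tibble(score = rbinom(n, 6, 0.4))
    d$clean <- rnorm(n)
    d$loaded <- 0.2 * d$score + rnorm(n)
    d$smoke <- rbinom(n, 1, 0.3)
  })
  rep <- confounder_balance(d, "score", c("clean", "loaded", "smoke"))
  expect_identical(rep$type, c("continuous", "continuous", "categorical"))
  expect_lt(rep$p_value[rep$confounder == "loaded"], 1e-6)
  expect_gt(rep$p_value[rep$confounder == "clean"], 0.001)
  empty <- confounder_balance(d, "score", character())
  expect_identical(nrow(empty), 0L)
})
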