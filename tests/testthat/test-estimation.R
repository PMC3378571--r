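test_that("OLS matches a normal-equations oracle on random designs", {
  withr::with_seed(1, {
    for (i in 1:10) {
      n <- 50
      d <- tibble::tibble(x = rnorm(n), c1 = rnorm(n), c2 = rnorm(n))
      d$y <- 1 + 0.5 * d$x - 0.3 * d$c1 + rnorm(n)
      fit <- ols_fit(d, "y", "x", c("c1", "c2"))
      xx <- cbind(1, d$x, d$c1, d$c2)
      beta_oracle <- solve(t(xx) %*% xx, t(xx) %*% d$y)
      resid <- d$y - xx %*% beta_oracle
      sigma2 <- sum(resid^2) / (n - 4)
      se_oracle <- sqrt(diag(sigma2 * solve(t(xx) %*% xx)))
      expect_equal(fit$beta, beta_oracle[2], tolerance = 1e-10)
      expect_equal(fit$se, se_oracle[2], tolerance = 1e-10)
    }
  })
})

test_that("OLS handles exact fits and rejects collinear designs", {
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10))
  fit <- ols_fit(d, "y", "x")
  expect_equal(fit$beta, 2, tolerance = 1e-12)
  expect_lt(fit$se, 1e-12)
  d$x2 <- 2 * d$x
  expect_error(ols_fit(d, "y", "x", "x2"), "[Cc]ollinear")
})

test_that("OLS null calibration: |beta| < 4 se nearly always under the null", {
  withr::with_seed(12, {
    inside <- vapply(1:300, function(i) {
      d <- tibble::tibble(x = rnorm(400), y = rnorm(400))
      f <- ols_fit(d, "y", "x")
      abs(f$beta) < 4 * f$se
    }, logical(1))
  })
  expect_gte(mean(inside), 0.99)
})

test_that("2SLS equals the Wald ratio on just-identified problems", {
  for (seed in 1:10) {
    d <- make_iv_data(300, beta = 0.4, seed = seed)
    iv <- tsls_fit(d, "y", "x", "z", f_floor = 0)
    expect_equal(iv$beta, wald_ratio(d, "y", "x", "z"), tolerance = 1e-10)
  }
})

test_that("2SLS is invariant to affine recoding of the instrument", {
  d <- make_iv_data(500, beta = 0.4, seed = 5)
  d$z2 <- 10 * d$z + 5
  f1 <- tsls_fit(d, "y", "x", "z", f_floor = 0)
  f2 <- tsls_fit(d, "y", "x", "z2", f_floor = 0)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f1$se, f2$se, tolerance = 1e-10)
  # and to flipping the dosage coding (absorbed by orientation downstream)
  d$zf <- 2 - d$z
  f3 <- tsls_fit(d, "y", "x", "zf", f_floor = 0)
  expect_equal(f1$beta, f3$beta, tolerance = 1e-10)
})

test_that("2SLS reduces to OLS in the exogenous limit Z = X", {
  d <- tibble::tibble(x = rnorm(100))
  d$z <- d$x
  d$y <- 2 * d$x
  iv <- tsls_fit(d, "y", "x", "z", f_floor = 0)
  expect_equal(iv$beta, 2, tolerance = 1e-10)
})

test_that("2SLS standard errors use IV residuals, not naive stage-2 ones", {
  d <- make_iv_data(2000, beta = 0.4, conf = 0.5, seed = 9)
  iv <- tsls_fit(d, "y", "x", "z", f_floor = 0)
  # oracle: textbook just-identified IV variance with residuals at observed x
  xx <- cbind(1, d$x); zz <- cbind(1, d$z)
  bhat <- solve(t(zz) %*% xx, t(zz) %*% d$y)
  u <- d$y - xx %*% bhat
  s2 <- sum(u^2) / (2000 - 2)
  pz <- zz %*% solve(t(zz) %*% zz, t(zz))
  vc <- s2 * solve(t(xx) %*% pz %*% xx)
  expect_equal(iv$beta, bhat[2], tolerance = 1e-10)
  expect_equal(iv$se, sqrt(vc[2, 2]), tolerance = 1e-10)
  # the naive second-stage OLS SE would differ
  naive <- ols_fit(dplyr::mutate(d, xh = fitted(lm(x ~ z, d))), "y", "xh")
  expect_false(isTRUE(all.equal(iv$se, naive$se, tolerance = 1e-4)))
})

test_that("2SLS weak-instrument policy: flag at F <= 10, error below floor", {
  d <- make_iv_data(150, beta = 0.3, r2 = 0.001, seed = 30)
  fs <- first_stage_fit(d, "x", "z")
  if (fs$f_statistic >= 1) {
    fit <- tsls_fit(d, "y", "x", "z")
    expect_true(fit$weak_instrument)
  }
  expect_error(tsls_fit(d, "y", "x", "z", f_floor = 1e6), "hard floor")
})

test_that("2SLS confidence interval is wider than OLS under a weak instrument", {
  d <- make_iv_data(3000, beta = 0.3, r2 = 0.03, seed = 17)
  d$ys <- standardize(d$y); d$xs <- standardize(d$x)
  iv <- tsls_fit(d, "ys", "xs", "z")
  ols <- ols_fit(d, "ys", "xs")
  expect_gt(iv$ci_high - iv$ci_low, ols$ci_high - ols$ci_low)
  expect_equal(iv$ci_high - iv$beta, qnorm(0.975) * iv$se)
})

test_that("Hausman augmented form equals the control-function t-test", {
  d <- make_iv_data(800, beta = 0.4, conf = 0.5, seed = 23)
  h <- durbin_hausman(d, "y", "x", "z")
  d$v <- residuals(lm(x ~ z, d))
  ct <- summary(lm(y ~ x + v, d))$coefficients["v", ]
  expect_equal(h$statistic, unname(ct["t value"]), tolerance = 1e-10)
  expect_equal(h$p_value, unname(ct["Pr(>|t|)"]), tolerance = 1e-10)
  expect_identical(h$form, "augmented_regression")
})

test_that("Hausman contrast form appears only with positive variance difference", {
  d <- make_iv_data(3000, beta = 0.4, conf = 0.5, seed = 31)
  h <- durbin_hausman(d, "y", "x", "z")
  expect_false(is.na(h$contrast_statistic))
  expect_gte(h$contrast_statistic, 0)
  # proportional outcome with the exposure as its own instrument: no
  # endogeneity information, statistic 0 by convention
  d2 <- tibble::tibble(x = rnorm(50))
  d2$z <- d2$x; d2$y <- 3 * d2$x
  h2 <- durbin_hausman(d2, "y", "x", "z")
  expect_equal(h2$statistic, 0)
  expect_equal(h2$p_value, 1)
})

test_that("Hausman power: strong confounding is detected", {
  reject <- vapply(1:100, function(i) {
    d <- make_iv_data(5000, beta = 0.3, conf = 0.5, r2 = 0.03, seed = 1000 + i)
    durbin_hausman(d, "y", "x", "z")$p_value < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.8)
})

test_that("partial correlation matches the precision-matrix identity", {
  withr::with_seed(3, {
    for (i in 1:8) {
      n <- 100
      d <- tibble::tibble(a = rnorm(n), b = rnorm(n), c1 = rnorm(n),
                          c2 = rnorm(n))
      d$a <- d$a + 0.5 * d$c1
      d$b <- d$b + 0.5 * d$c1 - 0.3 * d$c2
      pc <- partial_correlation(d, "a", "b", c("c1", "c2"))
      prec <- solve(cor(d[, c("a", "b", "c1", "c2")]))
      oracle <- -prec[1, 2] / sqrt(prec[1, 1] * prec[2, 2])
      expect_equal(pc$r, oracle, tolerance = 1e-10)
    }
  })
  # no covariates: plain Pearson
  d <- tibble::tibble(a = rnorm(50), b = rnorm(50))
  expect_equal(partial_correlation(d, "a", "b")$r, cor(d$a, d$b),
               tolerance = 1e-12)
  expect_equal(partial_correlation(d, "a", "b")$p_value,
               cor.test(d$a, d$b)$p.value, tolerance = 1e-10)
})

test_that("Fisher z comparison reproduces the closed form", {
  same <- fisher_z_compare(0.3, 100, 0.3, 200)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  a <- fisher_z_compare(0.5, 80, 0.2, 90)
  b <- fisher_z_compare(0.2, 90, 0.5, 80)
  expect_equal(a$z, -b$z)
  expect_equal(a$p_value, b$p_value)
  # sex comparison of weight-SUA correlations at published group sizes
  wt <- fisher_z_compare(0.33, 3251, 0.24, 2933)
  expect_equal(wt$z, (atanh(0.33) - atanh(0.24)) /
                 sqrt(1 / 3248 + 1 / 2930), tolerance = 1e-12)
  expect_equal(round(wt$z, 2), 3.85)
  expect_lt(wt$p_value, 0.001)
  expect_error(fisher_z_compare(1, 50, 0.2, 50), "< 1")
  expect_error(fisher_z_compare(0.5, 3, 0.2, 50), "exceed 3")
})

test_that("sex-interaction statistic follows the stated formula", {
  expect_equal(sex_interaction(0.5, 0.1, 0.5, 0.2)$z, 0)
  si <- sex_interaction(0.5, 0.1, 0.3, 0.1)
  expect_equal(si$z, 0.2 / sqrt(0.02), tolerance = 1e-12)
  expect_equal(round(si$z, 4), 1.4142)
  expect_equal(round(si$p_value, 3), 0.157)
  flipped <- sex_interaction(0.3, 0.1, 0.5, 0.1)
  expect_equal(flipped$z, -si$z)
  expect_error(sex_interaction(0.5, 0, 0.3, 0.1), "positive")
})
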