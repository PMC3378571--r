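---
title: "Bidirectional Mendelian randomization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional Mendelian randomization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bidirmr)
```

## The scientific question and the estimator

Serum uric acid (SUA) and adiposity are robustly correlated, with plausible
mechanisms in both causal directions. `bidirmr` asks the question twice with
instrumental variables: once with SUA as the exposure (instrumented by a
urate-associated *SLC2A9*-region SNP) and once with each adiposity trait as
the exposure (instrumented by an additive allele score over *FTO*, *MC4R*
and *TMEM18*-region SNPs). A genetic instrument is valid if it (i) predicts
the exposure, (ii) is independent of confounders, and (iii) affects the
outcome only through the exposure. The package checks (i) with the
first-stage F, probes (ii) with `confounder_balance()`, and — like all MR —
must assume (iii).

The estimator is two-stage least squares. With exposure $X$, outcome $Y$,
instrument $Z$ and exogenous covariates $C$:

$$X = \pi_0 + \pi_1 Z + \pi_2' C + v, \qquad
  Y = \beta_0 + \beta_1 \hat X + \beta_2' C + \varepsilon.$$

`tsls_fit()` reports $\hat\beta_1$ with the IV residual convention: the
error variance uses residuals at the *observed* exposure,
$\hat\sigma^2 = \|Y - X\hat\beta_{2SLS}\|^2/(n-p)$, and the covariance is
$\hat\sigma^2(\hat X'\hat X)^{-1}$. The naive second-stage OLS standard
error (residuals at $\hat X$) is wrong and is deliberately not used; a unit
test asserts the difference. On just-identified problems without covariates
the estimate equals the Wald ratio $\mathrm{cov}(Z,Y)/\mathrm{cov}(Z,X)$
exactly, which `wald_ratio()` provides as an independent cross-check.

Exogenous covariates enter **both** stages. This is the standard treatment
of included exogenous regressors in 2SLS (and the default of the major
econometrics implementations); projecting the exposure on the instrument
alone and then adjusting only the second stage would leave the first-stage
fitted values correlated with $C$ and bias $\hat\beta_1$.

All regressions use classical homoskedastic standard errors, t reference
distributions, and 95% CIs of $\hat\beta \pm 1.959964\,\mathrm{SE}$. No
robust or clustered variants are offered: the analysis this package
implements predates their routine use in MR, and offering them would change
the meaning of the published-style outputs.

## Endogeneity testing

`durbin_hausman()` compares OLS and 2SLS. The primary form is the
control-function (augmented) regression: regress $X$ on $Z$ (+ $C$), add the
first-stage residual $\hat v$ to the OLS outcome model, and t-test its
coefficient. This form is always well defined. The contrast form
$(\hat\beta_{IV}-\hat\beta_{OLS})^2/(\mathrm{SE}_{IV}^2-\mathrm{SE}_{OLS}^2)$
against $\chi^2_1$ matches the verbal description "compare the two
estimates" but is undefined when the variance difference is non-positive;
it is then suppressed with a note while the augmented form is still
returned. If the instrument reproduces the exposure exactly (zero
first-stage residual variance) the statistic is 0 and p = 1 by convention —
there is no endogeneity information in such data.

## Instruments

Each SNP is oriented so the counted allele associates with *higher* trait
values: if the in-sample regression slope of the (transformed) trait on the
dosage is negative, the coding flips ($d \to 2-d$). The allele score is the
unweighted sum over the instrument SNPs — an ordinal 0–6 variable for three
SNPs — and enters the first stage as a single linear regressor, not as
category indicators (the additive coding is the model; a single R² describes
it). Categories 0–2 are merged only for descriptive trend tables
(`collapse_low_categories()`), never for estimation.

`search_best_instrument()` enumerates every $\binom{m}{k}$ combination of
candidate SNPs, pooled across genes with no per-gene quota (the strongest
real-data combinations are sometimes all from one gene), and keeps the
combination with the largest crude first-stage F, breaking ties toward the
lexicographically smallest SNP set so the search is deterministic. Selection
always uses the covariate-free first stage; adjusted models additionally
report the partial F for the instrument block. Because orientation and
selection reuse the estimation sample, the winning F is optimistic and the
selected score can include noise SNPs whose spurious in-sample association
inflates the 2SLS denominator — visible in default-scale simulations as IV
estimates somewhat below the generative effect. This reproduces a
recognized overfitting risk of in-sample instrument selection;
`split_sample = TRUE` orients and selects on a random half and re-estimates
on the other half for an honest (but less precise) first stage. The default
is off, matching the single-sample design the package emulates.

The trend test across score categories is Cuzick's Wilcoxon-type test:
rank all observations, correlate rank with the ordinal group score, and
refer the standardized statistic to the normal distribution, with mid-ranks
and the usual tie correction. The source design names only "a non-parametric
test for trend"; Cuzick's is the standard epidemiological choice and its
type-I error is verified at 5% by simulation in the test suite.

## Preprocessing

- **Transformations** (fixed mapping): log for weight and waist, square
  root for SUA and fat mass, inverse square root for BMI. The BMI transform
  is *negated* ($-1/\sqrt{\mathrm{BMI}}$) so that, like the other four, the
  transformed value increases with the trait and regression signs keep
  their raw-direction meaning. Whether the original analysis negated the
  transform or re-signed coefficients afterwards is unknowable; negation is
  the convention here and is applied consistently.
- **Standardization** divides by the sample SD (n−1) *within each model's
  complete-case sample*, so each reported n governs its own scale. This is
  why crude and adjusted rows of the same cell can have slightly different
  ns (a missing covariate drops a row only from the adjusted model).
- **eGFR** comes from the abbreviated MDRD equation,
  $186 \cdot (\mathrm{crea}/88.4)^{-1.154} \cdot \mathrm{age}^{-0.203}
  \cdot F$, $F = 0.742$ for women, and is derived inside the pipeline from
  creatinine, age and sex.
- **QC**: samples with genotype call rate below 95% are removed first, then
  SNPs that are monomorphic, below 70% call rate, below 1% MAF, or with a
  Hardy–Weinberg chi-square p below `hwe_alpha`. All thresholds use strict
  "less than" semantics (a value exactly at the threshold is kept) and are
  configurable via `qc_thresholds()`. The HWE alpha is not part of the
  published description; the default is 1e-4, the conventional GWAS-QC
  choice, and the test is the 1-df chi-square (adequate at cohort-scale n;
  an exact test could be slotted in where counts are tiny). The single-pass
  order (samples, then SNPs) follows the usual array-QC narrative;
  `iterate = TRUE` alternates the two filters to an order-independent fixed
  point.

## The synthetic cohort generator

No individual-level data from the motivating study are distributable, so
`simulate_cohort()` generates cohorts with the structure the analysis
assumes. Latent standardized adiposity $A$ and SUA $S$ follow

$$A = b_{SA} S + \alpha_A\,\mathrm{score}_c + c_A U + e_A, \qquad
  S = b_{AS} A + \alpha_S g_c + c_S U + e_S,$$

with $U \sim N(0,1)$ a shared confounder, $\mathrm{score}_c$ the centered
causal allele score, $g_c$ the centered urate SNP. The genetic coefficients
are calibrated (`calibrate_effect()`) so the score and SNP explain exactly
the configured variance fractions — defaults 0.0060 and 0.0316, the
instrument strengths the analysis design targets. The causal coefficients
are switched on by `direction` (`null`, either single direction, or `both`,
in which case the simultaneous system is solved); residual variances are
solved analytically so both latents have population variance 1, and a
configuration whose loadings overspend that budget is rejected naming the
offending trait. The urate SNP always loads on SUA: instrument strength is
a property of the genotype–phenotype map, not of which causal direction is
active, and the reverse-direction null analysis requires it.

Design choices a user should know:

- **Confounding is a single latent $U$.** The six measured covariates (age,
  smoking, alcohol, diuretic use, creatinine; sex separately) are noisy
  functions of $U$, so adjustment removes only part of the confounding —
  the crude-vs-adjusted contrast stays meaningful. Sex is generated
  independently and shifts traits only through raw-scale location
  constants, which makes it a strong marginal correlate of both SUA and
  adiposity and lets adjusted models behave differently from crude ones in
  the realistic way.
- **Four measured adiposity traits** load on $A$ with fixed defaults
  (weight 0.98, waist 0.96, BMI 0.95, fat mass 0.93). A 2SLS analysis of a
  measured trait therefore targets $b_{AS}/\lambda$, a few percent above
  the latent effect; `expected_slopes()` computes both the OLS and IV
  population slopes from the generator's covariance algebra, and
  parameter-recovery tests compare simulation means against it.
- **Raw scale.** With `raw_scale = TRUE` (default) traits are mapped to
  raw units by inverting the analysis transformations around fixed
  sex-specific location/scale constants chosen to give means and SDs
  typical of a middle-aged European cohort (e.g. weight
  $= e^{4.39 + 0.18 A}$ kg for men). These constants are plumbing, not
  calibration targets; `raw_scale = FALSE` emits the standardized latents
  directly and is what the recovery simulations use, since the estimand is
  defined on that scale.
- **Missingness is MCAR**: per-SNP call rates, a small fraction (1%) of
  degraded-DNA samples with ~50% call rate for the sample filter to catch,
  and a 0.5% phenotype missingness rate. The default panel holds 24
  candidate SNPs at 98% call rate — with a small panel the per-sample call
  rate is granular (multiples of 1/24), so higher per-SNP missingness would
  make the 95% sample threshold degenerate; the resulting per-analysis ns
  (~5400 of 6184) land in the range the design contemplates.
- **No LD, no population structure, no imputation.** SNPs are independent;
  combinations are additive. Passing tests therefore validate the
  estimators and pipeline logic, *not* robustness to correlated
  instruments, stratification or informative missingness — on real data
  those remain the analyst's responsibility (principal-component columns,
  if present, are appended to the adjusted covariate set).

## Numerical conventions and degenerate inputs

- The first-stage F uses the exact identity $F = R^2(n-2)/(1-R^2)$ for a
  single regressor; $R^2 = 1$ yields an `Inf` sentinel rather than an
  error. `tsls_fit()` refuses to run below a hard F floor (default 1) and
  flags, but proceeds, at $F \le 10$ — stratified analyses with moderately
  weak instruments are part of the design.
- Collinear designs abort with a rank/condition-number diagnostic;
  monomorphic SNPs abort orientation (they should be QC-filtered);
  zero-variance vectors abort standardization; empty complete-case sets
  abort naming the most-missing variable.
- The pipeline is deterministic given its seed: instrument search breaks
  ties lexicographically, and the only randomized step (the optional
  half-sample split) draws from the seeded generator. Permuting sample
  order changes no estimate beyond floating-point noise (tested at 1e-10).

## Validation problem sizes

The test suite validates at sizes chosen to make Monte-Carlo error small
relative to the tolerances: genotype frequencies and calibration at
n = 1e5–2e5; first-stage F anchors at the published n (≈5200–5400) over 300
replicates; parameter recovery at n = 5000 over 500 replicates (mean 2SLS
within ±0.05 of a 0.30 SD/SD truth, OLS matching the algebraic bias to
±0.02, reverse-direction mean within ±0.03 of zero with 93–97% CI
coverage); test calibration (Durbin–Wu–Hausman, trend test) at 500
replicates against 5% ± 2%; and balance p-value uniformity by
Kolmogorov–Smirnov over 200 replicates.

## Known limitations

In-sample instrument selection is optimistic (see above); the generator's
single-confounder structure cannot represent confounders that affect only
one trait; the Durbin–Wu–Hausman test inherits the power limits of weak
instruments (a non-significant result with F ≈ 10–40 is weak evidence of
exogeneity); and the package deliberately omits LIML/GMM, robust SEs,
over-identification tests and meta-analytic SNP weighting — the design is
just-identified with unweighted scores throughout.
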