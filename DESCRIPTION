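Package: bidirmr
Title: Bidirectional Mendelian Randomization for Serum Uric Acid and Adiposity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Instrumental-variable analysis of the causal relationship between
    serum uric acid and adiposity markers using genetic instruments. Implements
    allele-score instrument construction and systematic combination search with
    first-stage F diagnostics, two-stage least squares in both causal
    directions with correct instrumental-variable standard errors,
    Durbin-Wu-Hausman endogeneity tests, nonparametric trend tests,
    confounder-balance checks, and auxiliary statistics (partial correlations,
    Fisher-z and sex-interaction comparisons). Includes a calibrated
    genotype-phenotype cohort simulator (Hardy-Weinberg genotypes, shared
    confounding, configurable causal direction, missingness and QC defects)
    for validation and parameter-recovery studies, plus quality-control
    filters, trait transformations and MDRD eGFR derivation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
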