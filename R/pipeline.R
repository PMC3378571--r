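#' Analysis configuration
#'
#' Options for the full bidirectional analysis: which causal directions,
#' adiposity traits, strata and model variants to run, the adjustment
#' covariate set, QC thresholds, and the allele-score combination size.
#'
#' @param directions Subset of `c("sua_to_adiposity", "adiposity_to_sua")`.
#' @param traits Subset of `c("weight", "bmi", "waist", "fat_mass")`.
#' @param strata Subset of `c("overall", "men", "women")`. Instruments are
#'   re-selected within each stratum; sex is dropped from the covariate list
#'   inside sex strata.
#' @param models Subset of `c("crude", "adjusted")`.
#' @param covariates Adjustment covariates (default age, sex, smoking,
#'   alcohol use, eGFR and diuretic use). Any phenotype columns starting
#'   with `"pc"` (ancestry principal components) are appended automatically
#'   when present.
#' @param qc [qc_thresholds()] applied before analysis.
#' @param k Combination size for the adiposity allele-score search
#'   (default 3).
#' @param alpha Two-sided significance level (0.05).
#' @param split_sample Orient/select instruments on a random half-sample
#'   (see [search_best_instrument()]).
#' @param seed Seed used for any randomized step (half-sample splits).
#' @return A list of class `mr_analysis_config`.
#' @export
analysis_config <- function(directions = c("sua_to_adiposity", "adiposity_to_sua"),
                            traits = c("weight", "bmi", "waist", "fat_mass"),
                            strata = c("overall", "men", "women"),
                            models = c("crude", "adjusted"),
                            covariates = c("age", "sex", "smoking", "alcohol",
                                           "gfr", "diuretic"),
                            qc = qc_thresholds(),
                            k = 3,
                            alpha = 0.05,
                            split_sample = FALSE,
                            seed = 1L) {
  directions <- match.arg(directions, c("sua_to_adiposity", "adiposity_to_sua"),
                          several.ok = TRUE)
  traits <- match.arg(traits, c("weight", "bmi", "waist", "fat_mass"),
                      several.ok = TRUE)
  strata <- match.arg(strata, c("overall", "men", "women"), several.ok = TRUE)
  models <- match.arg(models, c("crude", "adjusted"), several.ok = TRUE)
  structure(
    list(directions = directions, traits = traits, strata = strata,
         models = models, covariates = covariates, qc = qc,
         k = assert_count(k, "k"), alpha = alpha,
         split_sample = isTRUE(split_sample), seed = as.integer(seed)),
    class = "mr_analysis_config"
  )
}

# transformed-trait columns (.t_<trait>) added to the phenotype frame; when
# the cohort is on the latent standardized scale already, the transform is
# the identity
prepare_phenotypes <- function(cohort) {
  phen <- cohort$phenotypes
  raw <- is.null(cohort$config) || isTRUE(cohort$config$raw_scale)
  for (tr in names(trait_transform_map)) {
    if (!tr %in% names(phen)) next
    phen[[paste0(".t_", tr)]] <-
      if (raw) transform_trait(phen[[tr]], tr) else phen[[tr]]
  }
  if (all(c("creatinine", "age", "sex") %in% names(phen)) &&
      !"gfr" %in% names(phen)) {
    phen$gfr <- egfr_mdrd(phen$creatinine, phen$age, phen$sex)
  }
  phen
}

# one (trait, stratum) cell: select instrument, fit both models and methods
run_cell <- function(frame, exposure, outcome, candidates, k, covariates,
                     models, split_sample) {
  t_exp <- paste0(".t_", exposure)
  t_out <- paste0(".t_", outcome)
  search <- search_best_instrument(frame, t_exp, candidates, k = k,
                                   split_sample = split_sample)
  snps <- search$spec$snp_ids
  flips <- search$spec$orientation

  fit_model <- function(model) {
    covs <- if (model == "adjusted") covariates else NULL
    d <- complete_cases(frame, c(t_out, t_exp, snps, covs))
    for (i in seq_len(nrow(flips))) {
      if (flips$flipped[i]) d[[flips$snp_id[i]]] <- 2L - d[[flips$snp_id[i]]]
    }
    d <- build_score(d, snps, ".score")
    d$.y <- standardize(d[[t_out]])
    d$.x <- standardize(d[[t_exp]])
    list(
      model = model,
      ols = ols_fit(d, ".y", ".x", covs, model),
      tsls = tsls_fit(d, ".y", ".x", ".score", covs, model),
      hausman = durbin_hausman(d, ".y", ".x", ".score", covs),
      data = d
    )
  }
  fits <- lapply(models, fit_model)
  names(fits) <- models

  crude_like <- fits[[1]]$data
  balance <- confounder_balance(crude_like, ".score",
                                intersect(covariates, names(crude_like)))
  trend_frame <- crude_like
  trend_levels <- if (length(snps) >= 2) {
    collapse_low_categories(pmin(trend_frame$.score, 6L))
  } else factor(trend_frame$.score, ordered = TRUE)
  trend <- dplyr::bind_rows(
    dplyr::mutate(trend_test(trend_frame$.x, trend_levels), variable = "exposure"),
    dplyr::mutate(trend_test(trend_frame$.y, trend_levels), variable = "outcome")
  )
  list(search = search, fits = fits, balance = balance, trend = trend)
}

#' Run one causal direction of the Mendelian-randomization analysis
#'
#' For each requested stratum and adiposity trait: derives eGFR, selects the
#' instrument within the stratum (the single strongest urate SNP when SUA is
#' the exposure; the strongest k-SNP allele score per trait when adiposity
#' is the exposure), transforms and standardizes exposure and outcome on
#' each model's complete-case sample, fits crude and adjusted OLS and 2SLS,
#' runs the Durbin-Wu-Hausman comparison, checks instrument-confounder
#' balance, and computes descriptive trend tests. Cells whose best
#' instrument falls below the hard F floor are reported as errored rows and
#' the run continues.
#'
#' @param cohort A QC'd `mr_cohort` (see [qc_cohort()]).
#' @param direction `"sua_to_adiposity"` (SUA is the exposure) or
#'   `"adiposity_to_sua"` (each adiposity trait is the exposure).
#' @param config An [analysis_config()].
#' @return An `mr_direction_report`: tibbles `results` (one row per trait x
#'   stratum x model x method), `instruments` (per-cell winning instrument
#'   with F and R-squared), `balance`, `trend`, `interactions` (sex
#'   interaction z per trait/model when both sex strata ran) and `errors`.
#' @export
run_direction <- function(cohort, direction, config = analysis_config()) {
  direction <- match.arg(direction, c("sua_to_adiposity", "adiposity_to_sua"))
  phen <- prepare_phenotypes(cohort)
  pcs <- grep("^pc[0-9]*$", names(phen), value = TRUE)
  covariates <- c(config$covariates, pcs)
  info <- cohort$snp_info
  urate_snps <- info$snp_id[info$gene %in% "SLC2A9"]
  adip_snps <- info$snp_id[!info$gene %in% "SLC2A9"]

  results <- instruments <- balance <- trend <- errors <- list()
  fits_store <- list()

  for (stratum in config$strata) {
    keep <- if (stratum == "overall") rep(TRUE, nrow(phen)) else
      !is.na(phen$sex) & phen$sex == stratum
    covs_strat <- if (stratum == "overall") covariates else
      setdiff(covariates, "sex")
    snp_cols <- if (direction == "sua_to_adiposity") urate_snps else adip_snps
    frame <- dplyr::left_join(phen[keep, , drop = FALSE],
                              cohort$genotypes[, c("sample_id", snp_cols)],
                              by = "sample_id")

    # SUA-as-exposure uses one single-SNP instrument per stratum, shared by
    # all outcome traits; re-run per trait below reuses the same search
    for (trait in config$traits) {
      exposure <- if (direction == "sua_to_adiposity") "sua" else trait
      outcome <- if (direction == "sua_to_adiposity") trait else "sua"
      candidates <- if (direction == "sua_to_adiposity") urate_snps else adip_snps
      k_use <- if (direction == "sua_to_adiposity") 1L else config$k
      cell <- tryCatch(
        run_cell(frame, exposure, outcome, candidates, k_use, covs_strat,
                 config$models, config$split_sample),
        error = function(e) e
      )
      key <- paste(direction, trait, stratum, sep = ".")
      if (inherits(cell, "error")) {
        errors[[key]] <- tibble::tibble(trait = trait, stratum = stratum,
                                        message = conditionMessage(cell))
        next
      }
      fits_store[[key]] <- cell$fits
      instruments[[key]] <- tibble::tibble(
        trait = trait, stratum = stratum,
        snp_ids = paste(cell$search$spec$snp_ids, collapse = "+"),
        f_statistic = cell$search$fit$f_statistic,
        r_squared = cell$search$fit$r_squared,
        n = cell$search$fit$n,
        weak = cell$search$weak
      )
      balance[[key]] <- dplyr::mutate(cell$balance, trait = trait,
                                      stratum = stratum)
      trend[[key]] <- dplyr::mutate(cell$trend, trait = trait,
                                    stratum = stratum)
      results[[key]] <- purrr::map_dfr(cell$fits, function(fm) {
        fs <- fm$tsls$first_stage
        # weak-instrument diagnostic: partial F for the instrument block in
        # adjusted models, overall F in crude ones
        fs_f <- if (!is.na(fs$partial_f)) fs$partial_f else fs$f_statistic
        purrr::map_dfr(list(fm$ols, fm$tsls), function(ft) {
          tibble::tibble(
            trait = trait, stratum = stratum, model = fm$model,
            method = ft$method, beta = ft$beta, se = ft$se,
            ci_low = ft$ci_low, ci_high = ft$ci_high,
            p_value = ft$p_value, n = ft$n,
            first_stage_f = fs_f, first_stage_r2 = fs$r_squared,
            hausman_p = fm$hausman$p_value
          )
        })
      })
    }
  }

  results <- dplyr::bind_rows(results)
  interactions <- tibble::tibble()
  if (all(c("men", "women") %in% config$strata) && nrow(results)) {
    iv_rows <- results[results$method == "2SLS" &
                         results$stratum %in% c("men", "women"), ]
    interactions <- iv_rows |>
      tidyr::pivot_wider(id_cols = c("trait", "model"),
                         names_from = "stratum",
                         values_from = c("beta", "se")) |>
      dplyr::filter(!is.na(.data$beta_men) & !is.na(.data$beta_women)) |>
      dplyr::mutate(sex_interaction(.data$beta_men, .data$se_men,
                                    .data$beta_women, .data$se_women))
  }

  structure(
    list(direction = direction,
         results = results,
         instruments = dplyr::bind_rows(instruments),
         balance = dplyr::bind_rows(balance),
         trend = dplyr::bind_rows(trend),
         interactions = interactions,
         errors = dplyr::bind_rows(errors),
         fits = fits_store,
         config = config),
    class = "mr_direction_report"
  )
}

#' @export
print.mr_direction_report <- function(x, ...) {
  cat(sprintf("<mr_direction_report> direction: %s\n", x$direction))
  print(x$results, n = 20)
  if (nrow(x$errors)) {
    cat("errored cells:\n"); print(x$errors)
  }
  invisible(x)
}

#' Run the full bidirectional Mendelian-randomization analysis
#'
#' Applies genotype QC, then runs [run_direction()] for each requested
#' direction, and assembles the instrument-summary table (trait, stratum,
#' SNPs, F, R-squared — one row per selected instrument), all regression
#' results, and a run log (seed, package version, QC counts).
#'
#' @param cohort An `mr_cohort` (QC is applied internally).
#' @param config An [analysis_config()].
#' @return An `mr_report`: list with `directions` (named
#'   `mr_direction_report`s), `instruments`, `results`, `qc`, `log`.
#' @export
run_bidirectional <- function(cohort, config = analysis_config()) {
  if (!inherits(cohort, "mr_cohort")) abort("`cohort` must be an mr_cohort.")
  clean <- qc_cohort(cohort, config$qc)
  qc_rep <- attr(clean, "qc")
  reports <- list()
  for (i in seq_along(config$directions)) {
    dir <- config$directions[i]
    reports[[dir]] <- withr::with_seed(
      config$seed + i,
      run_direction(clean, dir, config)
    )
  }
  instruments <- purrr::map_dfr(reports, function(r) {
    dplyr::mutate(r$instruments, direction = r$direction, .before = 1)
  })
  results <- purrr::map_dfr(reports, function(r) {
    dplyr::mutate(r$results, direction = r$direction, .before = 1)
  })
  structure(
    list(directions = reports,
         instruments = instruments,
         results = results,
         qc = qc_rep,
         log = list(
           seed = config$seed,
           package_version = as.character(utils::packageVersion("bidirmr")),
           n_samples_in = nrow(cohort$phenotypes),
           n_samples_kept = nrow(clean$phenotypes),
           n_snps_in = nrow(cohort$snp_info),
           n_snps_kept = nrow(clean$snp_info),
           timestamp = NULL
         )),
    class = "mr_report"
  )
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("<mr_report> directions: %s; %d samples, %d SNPs after QC\n",
              paste(names(x$directions), collapse = ", "),
              x$log$n_samples_kept, x$log$n_snps_kept))
  print(x$instruments)
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits the result, instrument, balance, trend and interaction tables as
#' TSV files plus one machine-readable JSON bundle (all tables and the run
#' log) under `dir`.
#'
#' @param report An `mr_report` from [run_bidirectional()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "mr_report")) abort("`report` must be an mr_report.")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    results = file.path(dir, "results.tsv"),
    instruments = file.path(dir, "instruments.tsv"),
    json = file.path(dir, "report.json")
  )
  readr::write_tsv(report$results, paths[["results"]], progress = FALSE)
  readr::write_tsv(report$instruments, paths[["instruments"]], progress = FALSE)
  bundle <- list(
    log = report$log,
    instruments = report$instruments,
    results = report$results,
    balance = purrr::map(report$directions, "balance"),
    trend = purrr::map(report$directions, "trend"),
    interactions = purrr::map(report$directions, "interactions"),
    errors = purrr::map(report$directions, "errors")
  )
  jsonlite::write_json(bundle, paths[["json"]], digits = NA, auto_unbox = TRUE,
                       dataframe = "rows", pretty = TRUE)
  invisible(paths)
}
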