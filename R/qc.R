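#' Quality-control thresholds
#'
#' Thresholds for genotype QC, with "less than" exclusion semantics
#' throughout: samples with per-sample call rate below `sample_min_call` are
#' removed; SNPs are removed when monomorphic, when their call rate is below
#' `snp_min_call`, when their MAF is below `min_maf`, or when the
#' Hardy-Weinberg goodness-of-fit p-value falls below `hwe_alpha`.
#'
#' @param sample_min_call Minimum per-sample genotyping call rate (default 0.95).
#' @param snp_min_call Minimum per-SNP call rate (default 0.70).
#' @param min_maf Minimum minor allele frequency (default 0.01).
#' @param hwe_alpha Significance level of the HWE filter (default 1e-4, the
#'   conventional GWAS-QC choice).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(sample_min_call = 0.95, snp_min_call = 0.70,
                          min_maf = 0.01, hwe_alpha = 1e-4) {
  for (nm in c("sample_min_call", "snp_min_call", "min_maf", "hwe_alpha")) {
    assert_fraction(get(nm), nm)
  }
  structure(list(sample_min_call = sample_min_call,
                 snp_min_call = snp_min_call,
                 min_maf = min_maf, hwe_alpha = hwe_alpha),
            class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of observed genotype counts against
#' the Hardy-Weinberg expectation at the sample allele frequency. Monomorphic
#' input returns p = 1 by convention (such SNPs are caught by the MAF filter
#' instead).
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (reference homozygote, heterozygote,
#'   alternate homozygote). Vectorized.
#' @return A tibble with columns `chisq` and `p_value`.
#' @export
#' @examples
#' hwe_test(25, 50, 25) # exact HWE: chisq 0, p 1
#' hwe_test(30, 40, 30) # heterozygote deficit: chisq 4, p 0.0455
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (any(n < 1)) abort("Total genotype count must be >= 1.")
  p <- (2 * n_aa + n_Aa) / (2 * n)
  q <- 1 - p
  exp_counts <- cbind(n * q^2, n * 2 * p * q, n * p^2)
  obs <- cbind(n_AA, n_Aa, n_aa)
  mono <- p == 0 | p == 1
  chisq <- rep(0, length(n))
  ok <- !mono
  if (any(ok)) {
    chisq[ok] <- rowSums((obs[ok, , drop = FALSE] -
                            exp_counts[ok, , drop = FALSE])^2 /
                           exp_counts[ok, , drop = FALSE])
  }
  tibble::tibble(chisq = chisq,
                 p_value = ifelse(mono, 1, pchisq(chisq, df = 1,
                                                  lower.tail = FALSE)))
}

dosage_input <- function(x) {
  if (inherits(x, "mr_cohort")) cohort_dosages(x) else as.matrix(x)
}

#' Sample-level genotyping QC
#'
#' Flags samples whose genotype call rate across all SNPs is below the
#' threshold ("less than" semantics: a call rate exactly at the threshold is
#' kept).
#'
#' @param dosages A samples-by-SNPs dosage matrix (NA = missing) or an
#'   `mr_cohort`.
#' @param thresholds A [qc_thresholds()] object.
#' @return A tibble with one row per sample: `sample_id`, `call_rate`,
#'   `kept`.
#' @export
filter_samples <- function(dosages, thresholds = qc_thresholds()) {
  m <- dosage_input(dosages)
  if (ncol(m) < 1) abort("At least one SNP is required.")
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  call_rate <- unname(rowMeans(!is.na(m)))
  tibble::tibble(sample_id = ids, call_rate = call_rate,
                 kept = call_rate >= thresholds$sample_min_call)
}

#' SNP-level genotyping QC
#'
#' Flags SNPs that are monomorphic, under-called, rare, or out of
#' Hardy-Weinberg proportions, each with "less than" exclusion semantics.
#' Call rates are computed on the samples provided (apply [filter_samples()]
#' first to match the sample-then-SNP QC order).
#'
#' @inheritParams filter_samples
#' @return A tibble with one row per SNP: `snp_id`, `call_rate`, `maf`,
#'   `hwe_p`, `kept`, and `reason` (`NA` when kept; otherwise the first
#'   failing criterion among monomorphic / call_rate / maf / hwe).
#' @export
filter_snps <- function(dosages, thresholds = qc_thresholds()) {
  m <- dosage_input(dosages)
  if (nrow(m) < 1) abort("At least one sample is required.")
  stats_per_snp <- lapply(seq_len(ncol(m)), function(j) {
    g <- m[, j]
    obs <- g[!is.na(g)]
    call_rate <- length(obs) / length(g)
    if (length(obs) == 0) {
      return(tibble::tibble(call_rate = call_rate, maf = NA_real_,
                            hwe_p = NA_real_, monomorphic = TRUE))
    }
    p <- mean(obs) / 2
    maf <- min(p, 1 - p)
    counts <- tabulate(obs + 1L, nbins = 3L)
    hw <- hwe_test(counts[1], counts[2], counts[3])
    tibble::tibble(call_rate = call_rate, maf = maf, hwe_p = hw$p_value,
                   monomorphic = maf == 0)
  })
  res <- dplyr::bind_rows(stats_per_snp)
  res$snp_id <- colnames(m) %||% as.character(seq_len(ncol(m)))
  reason <- rep(NA_character_, nrow(res))
  reason[!is.na(res$hwe_p) & res$hwe_p < thresholds$hwe_alpha] <- "hwe"
  reason[!res$monomorphic & res$maf < thresholds$min_maf] <- "maf"
  reason[res$call_rate < thresholds$snp_min_call] <- "call_rate"
  reason[res$monomorphic] <- "monomorphic"
  res$kept <- is.na(reason)
  res$reason <- reason
  res[, c("snp_id", "call_rate", "maf", "hwe_p", "kept", "reason")]
}

#' Apply full genotype QC to a cohort
#'
#' Runs sample-level QC first, then SNP-level QC on the retained samples
#' (matching the usual array-QC narrative order); optionally iterates the two
#' filters to a fixed point. Returns the filtered cohort with the per-sample
#' and per-SNP verdict tables attached.
#'
#' @param cohort An `mr_cohort`.
#' @param thresholds A [qc_thresholds()] object.
#' @param iterate If `TRUE`, alternate sample and SNP filters until no
#'   further removals (order-independent result); default `FALSE` = single
#'   pass, samples first.
#' @return The QC'd `mr_cohort`, with a `qc` attribute holding the
#'   `samples` and `snps` report tibbles.
#' @export
qc_cohort <- function(cohort, thresholds = qc_thresholds(), iterate = FALSE) {
  if (!inherits(cohort, "mr_cohort")) abort("`cohort` must be an mr_cohort.")
  m <- cohort_dosages(cohort)
  keep_s <- rep(TRUE, nrow(m)); keep_v <- rep(TRUE, ncol(m))
  sample_report <- snp_report <- NULL
  repeat {
    rs <- filter_samples(m[keep_s, keep_v, drop = FALSE], thresholds)
    keep_s[keep_s] <- rs$kept
    rv <- filter_snps(m[keep_s, keep_v, drop = FALSE], thresholds)
    keep_v[keep_v] <- rv$kept
    sample_report <- if (is.null(sample_report)) rs else
      dplyr::rows_update(sample_report, rs, by = "sample_id")
    snp_report <- if (is.null(snp_report)) rv else
      dplyr::rows_update(snp_report, rv, by = "snp_id")
    if (!iterate || (all(rs$kept) && all(rv$kept))) break
  }
  snp_ids <- colnames(m)[keep_v]
  out <- new_mr_cohort(
    cohort$phenotypes[keep_s, , drop = FALSE],
    cohort$genotypes[keep_s, c("sample_id", snp_ids), drop = FALSE],
    cohort$snp_info[cohort$snp_info$snp_id %in% snp_ids, , drop = FALSE],
    cohort$config
  )
  attr(out, "qc") <- list(samples = sample_report, snps = snp_report)
  out
}
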