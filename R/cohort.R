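#' @rdname simulate_cohort
#' @param phenotypes,genotypes,snp_info,config Components of the container;
#'   see Value.
#' @export
new_mr_cohort <- function(phenotypes, genotypes, snp_info, config = NULL) {
  assert_columns(phenotypes, "sample_id", "phenotypes")
  assert_columns(genotypes, "sample_id", "genotypes")
  if (!identical(phenotypes$sample_id, genotypes$sample_id)) {
    abort("phenotypes and genotypes must be row-aligned on sample_id.")
  }
  dos <- as.matrix(genotypes[, setdiff(names(genotypes), "sample_id")])
  bad <- dos[!is.na(dos)]
  if (length(bad) && !all(bad %in% 0:2)) {
    abort("Dosages must be 0, 1, 2 or missing.")
  }
  structure(list(phenotypes = phenotypes, genotypes = genotypes,
                 snp_info = snp_info, config = config),
            class = "mr_cohort")
}

#' @export
print.mr_cohort <- function(x, ...) {
  cat(sprintf("<mr_cohort> %d samples, %d SNPs\n",
              nrow(x$phenotypes), nrow(x$snp_info)))
  cat("genes:", paste(unique(x$snp_info$gene), collapse = ", "), "\n")
  if (!is.null(x$config)) {
    cat(sprintf("synthetic (direction = %s, seed = %d)\n",
                x$config$params$direction, x$config$seed))
  }
  invisible(x)
}

# dosage matrix (samples x SNPs) with sample ids as rownames
cohort_dosages <- function(cohort) {
  g <- cohort$genotypes
  m <- as.matrix(g[, setdiff(names(g), "sample_id"), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- g$sample_id
  m
}

#' Write a cohort to VCF + phenotype TSV
#'
#' Emits `<out_prefix>.vcf` (VCF 4.2, one record per SNP, GT field only;
#' dosage 0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`, missing -> `./.`) and
#' `<out_prefix>.pheno.tsv` (tab-delimited phenotype/covariate table with a
#' header row). The pair round-trips losslessly through [read_cohort()].
#'
#' @param cohort An `mr_cohort`.
#' @param out_prefix Output path prefix.
#' @return Invisibly, a character vector of the two file paths written.
#' @export
write_cohort <- function(cohort, out_prefix) {
  if (!inherits(cohort, "mr_cohort")) abort("`cohort` must be an mr_cohort.")
  vcf_path <- paste0(out_prefix, ".vcf")
  tsv_path <- paste0(out_prefix, ".pheno.tsv")

  dos <- cohort_dosages(cohort)
  info <- cohort$snp_info
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = ncol(dos), ncol = nrow(dos))
  for (j in seq_len(ncol(dos))) {
    obs <- !is.na(dos[, j])
    gt[j, obs] <- gt_code[dos[obs, j] + 1L]
  }
  body <- vapply(seq_len(nrow(info)), function(j) {
    paste(c(info$gene[j], j, info$snp_id[j], "A", "G", ".", "PASS", ".",
            "GT", gt[j, ]), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bidirmr",
    paste0("##contig=<ID=", unique(info$gene), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dos)), collapse = "\t")
  )
  writeLines(c(header, body), vcf_path)
  readr::write_tsv(cohort$phenotypes, tsv_path, na = "NA", progress = FALSE)
  invisible(c(vcf = vcf_path, pheno = tsv_path))
}

#' Read a cohort from VCF + phenotype TSV
#'
#' Parses genotypes with vcfR (GT field; `./.` and half-calls become missing)
#' and the phenotype table with readr, aligning both on sample id. Samples
#' present in only one file are dropped with a warning.
#'
#' @param vcf_path Path to a VCF with biallelic SNPs and a GT field.
#' @param pheno_path Path to the tab-delimited phenotype table; must contain
#'   a `sample_id` column.
#' @return An `mr_cohort` (with `config = NULL`).
#' @export
read_cohort <- function(vcf_path, pheno_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
  clean <- gsub("|", "/", t(gt), fixed = TRUE)
  dos[clean == "0/0"] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean == "1/1"] <- 2L

  phen <- readr::read_tsv(pheno_path, show_col_types = FALSE, progress = FALSE)
  assert_columns(phen, "sample_id", "phenotype table")
  phen$sample_id <- as.character(phen$sample_id)
  if ("sex" %in% names(phen)) {
    phen$sex <- factor(phen$sex, levels = c("men", "women"))
  }

  common <- intersect(phen$sample_id, rownames(dos))
  if (length(common) < max(nrow(phen), nrow(dos))) {
    warn("Dropping samples present in only one of the VCF / phenotype table.")
  }
  phen <- phen[match(common, phen$sample_id), ]
  dos <- dos[common, , drop = FALSE]

  chrom <- vcfR::getCHROM(v)
  known <- c("FTO", "MC4R", "TMEM18", "SLC2A9")
  obs_maf <- apply(dos, 2, function(g) {
    p <- mean(g, na.rm = TRUE) / 2
    if (is.nan(p)) NA_real_ else min(p, 1 - p)
  })
  info <- tibble::tibble(
    snp_id = colnames(dos),
    gene = ifelse(chrom %in% known, chrom, NA_character_),
    maf = unname(obs_maf),
    call_rate = unname(colMeans(!is.na(dos))),
    hwe_inbreeding = NA_real_
  )
  genotypes <- dplyr::bind_cols(tibble::tibble(sample_id = common),
                                tibble::as_tibble(dos))
  new_mr_cohort(phen, genotypes, info, config = NULL)
}

#' Write / read a scenario configuration as YAML
#'
#' Serializes a [scenario_config()] (SNP panel, true parameters, missingness,
#' seed) to a YAML file and back, so simulation scenarios can be versioned as
#' plain text.
#'
#' @param config An `mr_scenario`.
#' @param path File path.
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()`
#'   returns an `mr_scenario` equal to the one written.
#' @export
write_scenario <- function(config, path) {
  if (!inherits(config, "mr_scenario")) abort("`config` must come from scenario_config().")
  out <- list(
    n_samples = config$n_samples,
    snps = lapply(seq_len(nrow(config$snps)), function(i) as.list(config$snps[i, ])),
    params = unclass(config$params),
    score_snps = as.list(config$score_snps),
    sua_snp = config$sua_snp,
    trait_loadings = as.list(config$trait_loadings),
    missing_rate_pheno = config$missing_rate_pheno,
    bad_sample_rate = config$bad_sample_rate,
    bad_sample_call = config$bad_sample_call,
    raw_scale = config$raw_scale,
    seed = config$seed
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  snps <- dplyr::bind_rows(lapply(raw$snps, tibble::as_tibble))
  scenario_config(
    n_samples = raw$n_samples,
    snps = snps,
    params = do.call(true_params, raw$params),
    score_snps = unlist(raw$score_snps),
    sua_snp = raw$sua_snp,
    trait_loadings = unlist(raw$trait_loadings),
    missing_rate_pheno = raw$missing_rate_pheno,
    bad_sample_rate = raw$bad_sample_rate,
    bad_sample_call = raw$bad_sample_call,
    raw_scale = raw$raw_scale,
    seed = raw$seed
  )
}
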