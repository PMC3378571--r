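# transformation applied to each trait before standardization; fixed mapping
trait_transform_map <- c(weight = "log", waist = "log",
                         sua = "sqrt", fat_mass = "sqrt",
                         bmi = "neg_inv_sqrt")

#' Estimated glomerular filtration rate (abbreviated MDRD equation)
#'
#' eGFR in ml/min/1.73 m^2 from serum creatinine, age and sex:
#' `186 * (creatinine / 88.4)^-1.154 * age^-0.203 * F`, with F = 1 for men
#' and F = 0.742 for women.
#'
#' @param creatinine_umol_l Serum creatinine in umol/L (> 0). Vectorized.
#' @param age_years Age in years (> 0).
#' @param sex Factor or character, `"men"`/`"women"` (or `"male"`/`"female"`).
#' @return Numeric vector of eGFR values.
#' @export
#' @examples
#' egfr_mdrd(88.4, 50, "men")   # 84.07
#' egfr_mdrd(88.4, 50, "women") # 62.38
egfr_mdrd <- function(creatinine_umol_l, age_years, sex) {
  ok_cr <- is.na(creatinine_umol_l) | creatinine_umol_l > 0
  ok_age <- is.na(age_years) | age_years > 0
  if (!all(ok_cr)) abort("Creatinine must be positive.")
  if (!all(ok_age)) abort("Age must be positive.")
  sx <- tolower(as.character(sex))
  female <- sx %in% c("women", "female", "f")
  male <- sx %in% c("men", "male", "m")
  if (!all(female | male | is.na(sx))) {
    abort("`sex` must be men/women (or male/female).")
  }
  186 * (creatinine_umol_l / 88.4)^(-1.154) * age_years^(-0.203) *
    ifelse(female, 0.742, 1)
}

#' Trait transformation toward normality
#'
#' Applies the fixed per-trait transformation used throughout the analysis:
#' natural log for weight and waist circumference, square root for serum
#' uric acid and fat mass, and negated inverse square root for BMI. The BMI
#' transform is negated so that the transformed value increases with BMI,
#' keeping regression signs interpretable in the raw direction for all five
#' traits.
#'
#' @param values Positive numeric vector (NA allowed, propagated).
#' @param kind Trait name (`"weight"`, `"waist"`, `"sua"`, `"fat_mass"`,
#'   `"bmi"`) or transformation name (`"log"`, `"sqrt"`, `"neg_inv_sqrt"`).
#' @return Transformed numeric vector.
#' @export
#' @examples
#' transform_trait(100, "weight") # log(100)
#' transform_trait(400, "sua")    # 20
#' transform_trait(25, "bmi")     # -0.2
transform_trait <- function(values, kind) {
  if (kind %in% names(trait_transform_map)) kind <- trait_transform_map[[kind]]
  kind <- match.arg(kind, c("log", "sqrt", "neg_inv_sqrt"))
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad)) {
    abort(sprintf("Non-positive value at position(s) %s: transform `%s` requires positive input.",
                  paste(utils::head(bad, 5), collapse = ", "), kind))
  }
  switch(kind,
         log = log(values),
         sqrt = sqrt(values),
         neg_inv_sqrt = -1 / sqrt(values))
}

#' Standardize to z-scores
#'
#' Centers and scales by the sample standard deviation (n - 1 denominator),
#' computed on the non-missing values supplied. In the analysis pipeline this
#' is applied after complete-case selection, so each model's own analysis
#' sample sets the scale.
#'
#' @param values Numeric vector with at least two distinct non-missing values.
#' @return Numeric vector with mean 0 and SD 1 over the non-missing entries.
#' @export
standardize <- function(values) {
  obs <- values[!is.na(values)]
  if (length(obs) < 2) abort("Need at least 2 non-missing values to standardize.")
  s <- sd(obs)
  if (s == 0) abort("Cannot standardize a zero-variance vector.")
  (values - mean(obs)) / s
}

#' Complete-case selection
#'
#' Restricts a data frame to rows non-missing on every listed variable —
#' the per-model analysis sample, whose size is reported alongside each
#' estimate.
#'
#' @param data A data frame (e.g. a joined phenotype + dosage table).
#' @param required Character vector of column names that must be non-missing.
#' @return The subset tibble; its `n` attribute records the retained count.
#' @export
complete_cases <- function(data, required) {
  assert_columns(data, required)
  keep <- complete.cases(data[, required, drop = FALSE])
  out <- tibble::as_tibble(data[keep, , drop = FALSE])
  if (nrow(out) == 0) {
    per_var <- vapply(required, function(v) sum(is.na(data[[v]])), integer(1))
    abort(sprintf("No complete cases; most missing variable: `%s` (%d missing).",
                  names(which.max(per_var)), max(per_var)))
  }
  attr(out, "n") <- nrow(out)
  out
}

# phenotype table joined with selected dosage columns, row-aligned on sample_id
analysis_frame <- function(cohort, snps = NULL) {
  out <- cohort$phenotypes
  if (length(snps)) {
    assert_columns(cohort$genotypes, snps, "genotypes")
    out <- dplyr::left_join(out, cohort$genotypes[, c("sample_id", snps)],
                            by = "sample_id")
  }
  out
}
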