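#' Tidy methods for fitted objects
#'
#' Broom-style one-row-per-term summaries: `tidy()` returns estimate-level
#' tibbles, `glance()` one-row model summaries.
#'
#' @param x An `mr_fit`, `first_stage_fit`, `hausman_test`,
#'   `instrument_search`, `mr_direction_report` or `mr_report`.
#' @param ... Unused.
#' @return A tibble.
#' @name bidirmr-tidiers
NULL

#' @rdname bidirmr-tidiers
#' @export
tidy.mr_fit <- function(x, ...) {
  tibble::tibble(
    term = x$term %||% "exposure", method = x$method, model = x$model,
    estimate = x$beta, std.error = x$se,
    conf.low = x$ci_low, conf.high = x$ci_high,
    p.value = x$p_value, n = x$n
  )
}

#' @rdname bidirmr-tidiers
#' @export
glance.mr_fit <- function(x, ...) {
  tibble::tibble(method = x$method, model = x$model, n = x$n,
                 weak_instrument = isTRUE(x$weak_instrument),
                 first_stage_f = x$first_stage$f_statistic %||% NA_real_,
                 first_stage_r2 = x$first_stage$r_squared %||% NA_real_)
}

#' @rdname bidirmr-tidiers
#' @export
tidy.first_stage_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, r.squared = x$r_squared,
                 statistic = x$f_statistic, partial_f = x$partial_f,
                 n = x$n, weak = x$weak)
}

#' @rdname bidirmr-tidiers
#' @export
tidy.hausman_test <- function(x, ...) {
  tibble::tibble(form = c("augmented_regression", "contrast"),
                 statistic = c(x$statistic, x$contrast_statistic),
                 p.value = c(x$p_value, x$contrast_p),
                 n = x$n)
}

#' @rdname bidirmr-tidiers
#' @export
tidy.instrument_search <- function(x, ...) x$evaluated

#' @rdname bidirmr-tidiers
#' @export
glance.instrument_search <- function(x, ...) {
  tibble::tibble(snp_ids = paste(x$spec$snp_ids, collapse = "+"),
                 k = x$k, n_evaluated = x$n_evaluated,
                 f_statistic = x$fit$f_statistic,
                 r_squared = x$fit$r_squared, n = x$fit$n, weak = x$weak)
}

#' @rdname bidirmr-tidiers
#' @export
tidy.mr_direction_report <- function(x, ...) {
  dplyr::mutate(x$results, direction = x$direction, .before = 1)
}

#' @rdname bidirmr-tidiers
#' @export
tidy.mr_report <- function(x, ...) x$results

#' @rdname bidirmr-tidiers
#' @export
glance.mr_report <- function(x, ...) {
  tibble::as_tibble(x$log[c("seed", "package_version", "n_samples_in",
                            "n_samples_kept", "n_snps_in", "n_snps_kept")])
}
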