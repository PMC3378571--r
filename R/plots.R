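#' Forest plot of OLS versus 2SLS estimates
#'
#' Side-by-side standardized coefficients with 95% confidence intervals for
#' every trait, stratum and model in a direction report — the visual version
#' of the causal-versus-confounded contrast: when the IV interval excludes
#' the OLS point, confounding (or reverse causation) is implicated.
#'
#' @param object An `mr_direction_report` or `mr_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_direction_report <- function(object, ...) {
  res <- object$results
  ggplot2::ggplot(res, ggplot2::aes(x = .data$beta, y = .data$trait,
                                    colour = .data$method)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::facet_grid(stratum ~ model) +
    ggplot2::labs(
      title = sprintf("Direction: %s", object$direction),
      x = "standardized beta (95% CI)", y = NULL, colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mr_direction_report
#' @export
autoplot.mr_report <- function(object, ...) {
  res <- object$results
  ggplot2::ggplot(res, ggplot2::aes(x = .data$beta, y = .data$trait,
                                    colour = .data$method)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::facet_grid(stratum + model ~ direction) +
    ggplot2::labs(x = "standardized beta (95% CI)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot instrument strength across evaluated SNP combinations
#'
#' Histogram of first-stage F statistics over every combination evaluated by
#' [search_best_instrument()], with the weak-instrument threshold (F = 10)
#' and the winning combination marked.
#'
#' @param search An `instrument_search`.
#' @return A ggplot object.
#' @export
plot_instrument_search <- function(search) {
  ev <- search$evaluated
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$f_statistic)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = 10, linetype = 2) +
    ggplot2::geom_vline(xintercept = search$fit$f_statistic,
                        colour = "red") +
    ggplot2::labs(x = "first-stage F", y = "combinations",
                  title = sprintf("%d combinations of %d SNPs",
                                  search$n_evaluated, search$k)) +
    ggplot2::theme_minimal()
}
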