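#' Tidy a logistic fit into an odds-ratio table
#'
#' @param x A `logistic_fit`.
#' @param exponentiate Report odds ratios (default) or log-odds.
#' @param conf.level Confidence level for Wald intervals.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.logistic_fit <- function(x, exponentiate = TRUE, conf.level = 0.95, ...) {
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  z <- qnorm(1 - (1 - conf.level) / 2)
  out <- tibble::tibble(
    term = names(est),
    estimate = est,
    std.error = se,
    statistic = est / se,
    p.value = 2 * pnorm(abs(est / se), lower.tail = FALSE),
    conf.low = est - z * se,
    conf.high = est + z * se
  )
  if (exponentiate) {
    out <- dplyr::mutate(out,
                         estimate = exp(.data$estimate),
                         conf.low = exp(.data$conf.low),
                         conf.high = exp(.data$conf.high))
  }
  out
}

#' @rdname tidy.logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(n_used = x$n_used, n_dropped = x$n_dropped,
                 converged = x$converged, weighted = x$weighted,
                 deviance = x$glm$deviance, df.residual = x$glm$df.residual)
}

#' Tidy a Rubin-pooled estimate
#'
#' @param x A `pooled_estimate`.
#' @param exponentiate Report odds ratios instead of log-odds.
#' @param ... Unused.
#' @return The pooled tibble, optionally exponentiated.
#' @export
tidy.pooled_estimate <- function(x, exponentiate = FALSE, ...) {
  out <- tibble::as_tibble(x)
  if (exponentiate) {
    out <- dplyr::mutate(out,
                         estimate = exp(.data$estimate),
                         conf.low = exp(.data$conf.low),
                         conf.high = exp(.data$conf.high))
  }
  out
}

#' @rdname tidy.pooled_estimate
#' @export
glance.pooled_estimate <- function(x, ...) {
  tibble::tibble(M = attr(x, "M"), n_terms = nrow(x),
                 max_between = max(x$between), max_fmi = max(
                   (1 + 1 / attr(x, "M")) * x$between / x$total))
}

#' Tidy a survival curve
#'
#' @param x A `survival_curve`.
#' @param ... Unused.
#' @return The step-curve tibble (`time`, `n_risk`, `n_event`, `surv`, ...).
#' @export
tidy.survival_curve <- function(x, ...) x$curve

#' Tidy or summarise a comparison report
#'
#' `tidy()` returns the combined odds-ratio table (univariable and
#' multivariable, all methods); `glance()` the per-method ten-year survival
#' and model sizes.
#'
#' @param x A `comparison_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.comparison_report <- function(x, ...) {
  dplyr::bind_rows(x$univariable, x$multivariable)
}

#' @rdname tidy.comparison_report
#' @export
glance.comparison_report <- function(x, ...) {
  dplyr::left_join(x$survival, x$n_table, by = "method")
}
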