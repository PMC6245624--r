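#' Plot a Kaplan–Meier curve
#'
#' @param object A `survival_curve`.
#' @param ... Unused.
#' @return A ggplot: survival step function with the confidence band.
#' @export
autoplot.survival_curve <- function(object, ...) {
  d <- object$curve
  d0 <- dplyr::bind_rows(
    tibble::tibble(time = 0, surv = 1, conf.low = 1, conf.high = 1), d
  )
  ggplot2::ggplot(d0, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         alpha = 0.2, stat = "identity") +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years since enrolment", y = "Survival probability",
                  title = "Kaplan–Meier survival (LTF censored at last visit)") +
    ggplot2::theme_minimal()
}

#' Chain trace plot for an imputation set
#'
#' Mean of the imputed values per iteration, one line per imputation
#' stream and one panel per variable. A well-mixed chain shows no
#' discernible trend across iterations.
#'
#' @param object An `imputation_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.imputation_set <- function(object, ...) {
  ggplot2::ggplot(object$chain_history,
                  ggplot2::aes(x = .data$iteration, y = .data$mean,
                               group = .data$imputation,
                               colour = factor(.data$imputation))) +
    ggplot2::geom_line(alpha = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~ variable, scales = "free_y") +
    ggplot2::labs(x = "Chained-equation iteration",
                  y = "Mean of imputed values",
                  title = "Imputation chain traces") +
    ggplot2::theme_minimal()
}

#' Density of imputed versus observed values
#'
#' Overlays, for one continuous variable, the observed distribution and
#' the imputed values of each completed dataset — the standard visual
#' check that imputations are plausible.
#'
#' @param imp An `imputation_set`.
#' @param observed The `observed_cohort` it came from.
#' @param variable `"cd4"` or `"weight_kg"`.
#' @param max_sets Number of completed datasets to draw (default 5).
#' @return A ggplot.
#' @export
plot_imputed_density <- function(imp, observed, variable = c("cd4", "weight_kg"),
                                 max_sets = 5) {
  variable <- match.arg(variable)
  mask <- imp$missing_mask[[variable]]
  if (!any(mask)) abort(paste0("no imputed values for ", variable))
  sets <- head(seq_along(imp$datasets), max_sets)
  imp_d <- dplyr::bind_rows(lapply(sets, function(m) {
    tibble::tibble(value = imp$datasets[[m]][[variable]][mask],
                   source = paste0("imputed #", m))
  }))
  obs_d <- tibble::tibble(value = observed[[variable]][!mask],
                          source = "observed")
  ggplot2::ggplot(dplyr::bind_rows(obs_d, imp_d),
                  ggplot2::aes(x = .data$value, colour = .data$source,
                               linewidth = .data$source == "observed")) +
    ggplot2::geom_density() +
    ggplot2::scale_linewidth_manual(values = c(`TRUE` = 1, `FALSE` = 0.4),
                                    guide = "none") +
    ggplot2::labs(x = variable, y = "Density",
                  title = paste0("Imputed vs observed: ", variable)) +
    ggplot2::theme_minimal()
}

#' Forest plot of a method comparison
#'
#' Multivariable odds ratios with confidence intervals, one colour per
#' method.
#'
#' @param object A `comparison_report`.
#' @param model `"multivariable"` (default) or `"univariable"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.comparison_report <- function(object, model = "multivariable", ...) {
  d <- if (model == "multivariable") object$multivariable else object$univariable
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$term,
                                  colour = .data$method)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio for death by 10 years (log scale)",
                  y = NULL, colour = "Method") +
    ggplot2::theme_minimal()
}
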