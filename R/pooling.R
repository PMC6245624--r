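#' Attach the reporting-scale covariate columns
#'
#' Adds `age10` (age / 10 years), `weight10` (weight / 10 kg) and `cd4_100`
#' (CD4 / 100 cells) so fitted odds ratios are per 10-year, 10-kg and
#' 100-cell differences. The frame is flagged so a second application
#' errors instead of silently rescaling.
#'
#' @param data A data frame with `age_years`, `weight_kg` and `cd4`.
#' @return The same tibble with the scaled columns and a scaling flag.
#' @examples
#' cfg <- generator_config(n_patients = 50, seed = 2)
#' scale_covariates(generate_cohort(cfg))
#' @export
scale_covariates <- function(data) {
  if (isTRUE(attr(data, "ltfmice_scaled"))) {
    abort("covariates are already on the reporting scale; refusing to rescale",
          class = "ltfmice_schema_error")
  }
  needed <- c("age_years", "weight_kg", "cd4")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("scale_covariates needs column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ltfmice_schema_error")
  }
  data <- dplyr::mutate(tibble::as_tibble(data),
                        age10 = .data$age_years / 10,
                        weight10 = .data$weight_kg / 10,
                        cd4_100 = .data$cd4 / 100)
  attr(data, "ltfmice_scaled") <- TRUE
  data
}

#' Logistic regression with optional inverse-probability weights
#'
#' Weighted maximum-likelihood logistic regression (IRLS via [stats::glm]).
#' Rows with any missing model variable are dropped and counted. When
#' weights are supplied the covariance is the robust sandwich estimator
#' ([sandwich::vcovHC], HC0), since model-based standard errors are
#' anti-conservative under inverse-probability weighting.
#'
#' @param data A data frame containing the outcome and predictors.
#' @param formula Model formula, e.g. `dead10 ~ female + age10`.
#' @param weights Optional positive per-row weights (aligned with `data`).
#' @return An object of class `logistic_fit` with `coefficients`, `vcov`,
#'   `n_used`, `n_dropped`, `converged`, and `weighted`. Use [tidy()] for
#'   the odds-ratio table.
#' @examples
#' d <- tibble::tibble(dead10 = rbinom(100, 1, 0.3), x = rnorm(100))
#' tidy(logistic_fit(d, dead10 ~ x))
#' @export
logistic_fit <- function(data, formula, weights = NULL) {
  data <- tibble::as_tibble(data)
  vars <- all.vars(formula)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("model variables absent from data: ",
                 paste(missing_cols, collapse = ", ")),
          class = "ltfmice_schema_error")
  }
  keep <- complete.cases(data[vars])
  if (!is.null(weights)) {
    if (length(weights) != nrow(data)) {
      abort("weights must align with data rows", class = "ltfmice_model_error")
    }
    keep <- keep & !is.na(weights)
  }
  n_dropped <- sum(!keep)
  d <- data[keep, vars]
  if (nrow(d) == 0) {
    abort("no complete rows left to fit", class = "ltfmice_model_error")
  }
  w <- if (is.null(weights)) rep(1, nrow(d)) else weights[keep]
  if (any(!is.finite(w)) || any(w <= 0)) {
    abort("weights must be finite and positive", class = "ltfmice_model_error")
  }
  y <- d[[vars[1]]]
  if (length(unique(y)) < 2) {
    abort("outcome has a single class in the analyzable rows",
          class = "ltfmice_model_error")
  }
  d$.w <- w
  family <- if (is.null(weights)) binomial() else stats::quasibinomial()
  fit <- glm(formula, family = family, data = d, weights = .w,
             control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  if (!fit$converged || any(abs(coef(fit)) > 30)) {
    abort("logistic fit did not converge (possible separation)",
          class = "ltfmice_model_error")
  }
  vc <- if (is.null(weights)) {
    # binomial ML covariance from the Fisher information
    summary(fit)$cov.unscaled
  } else {
    sandwich::vcovHC(fit, type = "HC0")
  }
  structure(
    list(coefficients = coef(fit), vcov = vc,
         n_used = nrow(d), n_dropped = n_dropped,
         converged = fit$converged,
         weighted = !is.null(weights),
         formula = formula, glm = fit),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> n =", x$n_used,
      if (x$n_dropped > 0) paste0("(", x$n_dropped, " dropped)") else "",
      if (x$weighted) "[IPW, sandwich covariance]" else "", "\n")
  print(round(exp(x$coefficients), 3))
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Combines M per-imputation coefficient vectors: pooled point estimate
#' qbar = mean of the M estimates, within-imputation variance W = mean of
#' the M variances, between-imputation variance B = sample variance of the
#' estimates, total variance T = W + (1 + 1/M) B. Degrees of freedom use
#' the Barnard–Rubin small-sample correction when the complete-data
#' degrees of freedom are supplied, otherwise the classic large-sample
#' formula.
#'
#' @param estimates M-row matrix (or list of vectors) of coefficient
#'   estimates, columns = terms.
#' @param covariances List of M covariance matrices.
#' @param dfcom Optional complete-data degrees of freedom (n - p).
#' @param conf.level Confidence level for the pooled intervals.
#' @return A tibble of class `pooled_estimate`: one row per term with
#'   `estimate`, `within`, `between`, `total`, `std.error`, `df`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high` (log-odds scale).
#' @examples
#' rubin_pool(rbind(c(x = 0), c(x = 2)), list(matrix(1), matrix(1)))
#' @export
rubin_pool <- function(estimates, covariances, dfcom = NULL, conf.level = 0.95) {
  if (is.list(estimates) && !is.data.frame(estimates)) {
    estimates <- do.call(rbind, estimates)
  }
  estimates <- as.matrix(estimates)
  M <- nrow(estimates)
  if (M < 2) {
    abort("Rubin pooling needs M >= 2 imputations", class = "ltfmice_pool_error")
  }
  if (length(covariances) != M) {
    abort("need one covariance matrix per imputation", class = "ltfmice_pool_error")
  }
  terms <- colnames(estimates) %||% paste0("b", seq_len(ncol(estimates)))

  qbar <- unname(colMeans(estimates))
  W <- unname(Reduce(`+`, lapply(covariances, function(v) diag(as.matrix(v)))) / M)
  B <- unname(apply(estimates, 2, var))
  Tv <- W + (1 + 1 / M) * B

  # degrees of freedom per coefficient
  lambda <- pmin(pmax(((1 + 1 / M) * B) / Tv, 1e-12), 1 - 1e-12)
  df_old <- (M - 1) / lambda^2
  df <- if (!is.null(dfcom)) {
    df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
    df_old * df_obs / (df_old + df_obs)
  } else {
    df_old
  }

  se <- sqrt(Tv)
  tcrit <- qt(1 - (1 - conf.level) / 2, df)
  out <- tibble::tibble(
    term = terms,
    estimate = qbar,
    within = W,
    between = B,
    total = Tv,
    std.error = se,
    df = df,
    statistic = qbar / se,
    p.value = 2 * pt(abs(qbar / se), df, lower.tail = FALSE),
    conf.low = qbar - tcrit * se,
    conf.high = qbar + tcrit * se
  )
  class(out) <- c("pooled_estimate", class(out))
  attr(out, "M") <- M
  out
}

#' Kaplan–Meier survival curve
#'
#' Product-limit survival estimate with Greenwood variance (via
#' [survival::survfit]). Patients lost to follow-up should carry their
#' last-visit time with `event = 0` — the censoring convention under which
#' the estimator assumes loss is unrelated to mortality.
#'
#' @param times Non-negative follow-up times (years).
#' @param events 1 = death at `times`, 0 = censored at `times`.
#' @param conf.level Confidence level.
#' @return An object of class `survival_curve`: tibble `curve` columns
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`, `std_err`,
#'   `conf.low`, `conf.high`, plus the estimate at 10 years.
#' @examples
#' km <- km_survival(c(1, 2, 3, 4), c(1, 1, 0, 0))
#' surv_at(km, 2)
#' @export
km_survival <- function(times, events, conf.level = 0.95) {
  if (any(times < 0) || anyNA(times)) {
    abort("times must be non-negative and non-missing", class = "ltfmice_km_error")
  }
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.int = conf.level, conf.type = "log")
  curve <- tibble::tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    surv = fit$surv,
    std_err = fit$surv * fit$std.err,  # Greenwood SE of S(t)
    conf.low = fit$lower,
    conf.high = fit$upper
  )
  structure(list(curve = curve, n = length(times),
                 conf.level = conf.level),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  s10 <- surv_at(x, 10)
  cat("<survival_curve> n =", x$n, "| S(10) =", round(s10$surv, 3),
      sprintf("(%g%% CI %.3f-%.3f)\n", 100 * x$conf.level,
              s10$conf.low, s10$conf.high))
  invisible(x)
}

#' Survival probability at a given time from a curve
#'
#' @param curve A `survival_curve`.
#' @param t Time point.
#' @return One-row tibble with `time`, `surv`, `conf.low`, `conf.high`.
#' @export
surv_at <- function(curve, t) {
  stopifnot(inherits(curve, "survival_curve"))
  idx <- which(curve$curve$time <= t)
  if (length(idx) == 0) {
    return(tibble::tibble(time = t, surv = 1, conf.low = 1, conf.high = 1))
  }
  row <- curve$curve[max(idx), ]
  tibble::tibble(time = t, surv = row$surv,
                 conf.low = row$conf.low, conf.high = row$conf.high)
}

#' Ten-year survival under each analytic method
#'
#' A generic returning the proportion alive at ten years with a 95%
#' confidence interval, dispatched on the method's natural input:
#' * `survival_curve` — the Kaplan–Meier product-limit estimate at 10
#'   years (log-scale CI);
#' * `imputation_set` — the Rubin-pooled mean of the alive indicator
#'   across the M completed datasets;
#' * `data.frame` (a cohort of complete cases) with `weights` — the
#'   IPW-weighted alive proportion, with a robust (sandwich) interval.
#'
#' @param x Method input (see above).
#' @param ... Method-specific arguments.
#' @return A one-row tibble with `method`, `estimate`, `conf.low`,
#'   `conf.high`, `n`.
#' @export
survival_at_10 <- function(x, ...) UseMethod("survival_at_10")

#' @rdname survival_at_10
#' @export
survival_at_10.survival_curve <- function(x, ...) {
  s <- surv_at(x, 10)
  tibble::tibble(method = "km", estimate = s$surv,
                 conf.low = s$conf.low, conf.high = s$conf.high, n = x$n)
}

#' @rdname survival_at_10
#' @export
survival_at_10.imputation_set <- function(x, ...) {
  M <- length(x$datasets)
  props <- vapply(x$datasets, function(d) mean(1 - d$dead10), numeric(1))
  vars <- vapply(x$datasets, function(d) {
    p <- mean(1 - d$dead10)
    p * (1 - p) / nrow(d)
  }, numeric(1))
  pooled <- rubin_pool(matrix(props, ncol = 1, dimnames = list(NULL, "alive")),
                       lapply(vars, function(v) matrix(v)),
                       dfcom = x$n - 1)
  tibble::tibble(method = "mice", estimate = pooled$estimate,
                 conf.low = pooled$conf.low, conf.high = pooled$conf.high,
                 n = x$n)
}

#' @rdname survival_at_10
#' @param weights Per-row weights for the complete cases (IPW method).
#' @export
survival_at_10.data.frame <- function(x, weights, ...) {
  if (missing(weights) || is.null(weights)) {
    abort("IPW survival needs per-row weights", class = "ltfmice_ipw_error")
  }
  if (anyNA(x$dead10)) {
    abort("IPW survival expects complete cases (no missing outcome)",
          class = "ltfmice_ipw_error")
  }
  alive <- 1 - x$dead10
  fit <- logistic_fit(tibble::tibble(alive = alive), alive ~ 1, weights = weights)
  ci <- plogis(fit$coefficients[1] + c(-1, 1) * qnorm(0.975) * sqrt(fit$vcov[1, 1]))
  tibble::tibble(method = "ipw",
                 estimate = sum(weights * alive) / sum(weights),
                 conf.low = ci[1], conf.high = ci[2], n = nrow(x))
}
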