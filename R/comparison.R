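# Odds-ratio tables shared by all four methods: one univariable model per
# predictor plus the fully adjusted model, Wald CIs on the log-odds scale.

fit_or_tables <- function(data, predictors, weights = NULL, method,
                          conf.level = 0.95) {
  z <- qnorm(1 - (1 - conf.level) / 2)
  one_model <- function(model_name, terms) {
    fml <- as.formula(paste("dead10 ~", paste(terms, collapse = " + ")))
    fit <- logistic_fit(data, fml, weights = weights)
    terms_out <- names(fit$coefficients)[-1]
    est <- unname(fit$coefficients[-1])
    se <- unname(sqrt(diag(fit$vcov))[-1])
    tibble::tibble(
      method = method, model = model_name, term = terms_out,
      or = exp(est), conf.low = exp(est - z * se), conf.high = exp(est + z * se),
      p.value = 2 * pnorm(abs(est / se), lower.tail = FALSE),
      n = fit$n_used
    )
  }
  uni <- dplyr::bind_rows(lapply(predictors, function(p) one_model(p, p)))
  multi <- one_model("multivariable", predictors)
  list(univariable = uni, multivariable = multi)
}

pooled_or_tables <- function(datasets, predictors, method, mask_keep = NULL,
                             conf.level = 0.95) {
  M <- length(datasets)
  one_model <- function(model_name, terms) {
    fml <- as.formula(paste("dead10 ~", paste(terms, collapse = " + ")))
    fits <- lapply(datasets, function(d) {
      if (!is.null(mask_keep)) d <- d[mask_keep, , drop = FALSE]
      logistic_fit(scale_covariates(d), fml)
    })
    n_used <- fits[[1]]$n_used
    est <- do.call(rbind, lapply(fits, function(f) f$coefficients))
    vcovs <- lapply(fits, function(f) f$vcov)
    pooled <- rubin_pool(est, vcovs, dfcom = n_used - ncol(est))
    pooled <- pooled[pooled$term != "(Intercept)", ]
    tibble::tibble(
      method = method, model = model_name, term = pooled$term,
      or = exp(pooled$estimate),
      conf.low = exp(pooled$conf.low), conf.high = exp(pooled$conf.high),
      p.value = pooled$p.value, n = n_used
    )
  }
  uni <- dplyr::bind_rows(lapply(predictors, function(p) one_model(p, p)))
  multi <- one_model("multivariable", predictors)
  list(univariable = uni, multivariable = multi)
}

new_method_result <- function(method, survival, tables, details = list()) {
  structure(list(method = method, survival = survival,
                 univariable = tables$univariable,
                 multivariable = tables$multivariable,
                 details = details),
            class = "method_result")
}

#' @export
print.method_result <- function(x, ...) {
  cat("<method_result>", x$method, "| multivariable n =",
      x$multivariable$n[1], "\n")
  print(dplyr::select(x$multivariable, "term", "or", "conf.low", "conf.high"))
  invisible(x)
}

#' Complete-case analysis
#'
#' Drops patients with unknown vital status (LTF) from the outcome and, per
#' model, every row with a missing covariate — the default behaviour of
#' most statistical software. Univariable model sizes therefore vary by
#' predictor, and the fully adjusted model is the smallest.
#'
#' @param observed An `observed_cohort` (fold tracing first if traced
#'   outcomes should count as documented).
#' @param predictors Character vector of reporting-scale predictors.
#' @return A `method_result` with survival (simple proportion alive among
#'   outcome-known patients, Wald CI), univariable and multivariable
#'   odds-ratio tables.
#' @export
run_complete_case <- function(observed, predictors = default_predictors()) {
  stopifnot(inherits(observed, "observed_cohort"))
  known <- dplyr::filter(observed, .data$status != "ltf")
  if (nrow(known) == 0) {
    abort("no patients with known outcome; complete-case analysis impossible",
          class = "ltfmice_model_error")
  }
  d <- scale_covariates(known)
  tables <- fit_or_tables(d, predictors, method = "cc")
  p_alive <- mean(1 - known$dead10)
  se <- sqrt(p_alive * (1 - p_alive) / nrow(known))
  survival <- tibble::tibble(method = "cc", estimate = p_alive,
                             conf.low = p_alive - qnorm(0.975) * se,
                             conf.high = p_alive + qnorm(0.975) * se,
                             n = nrow(known))
  new_method_result("cc", survival, tables,
                    details = list(n_known = nrow(known),
                                   n_ltf_dropped = sum(observed$status == "ltf")))
}

#' Tracing-based inverse-probability-weighted analysis
#'
#' Folds tracing results into the cohort, derives the deaths-among-LTF
#' estimate, weights every outcome-known patient by the inverse probability
#' of a documented outcome in their (dead/alive) stratum, and fits weighted
#' logistic models with robust covariance. LTF patients never found remain
#' excluded. `weights_type = "covariate"` instead uses the
#' covariate-conditional completeness model of [covariate_ipw_weights()].
#'
#' @param observed An `observed_cohort` (tracing not yet folded).
#' @param tracing A [tracing_result()] with per-patient records.
#' @param predictors Reporting-scale predictors.
#' @param weights_type `"stratum"` (default) or `"covariate"`.
#' @param completeness_formula Covariates for the completeness model when
#'   `weights_type = "covariate"`.
#' @return A `method_result`; the stratum table or completeness fit is in
#'   `details`, alongside the per-patient weights.
#' @export
run_ipw <- function(observed, tracing, predictors = default_predictors(),
                    weights_type = c("stratum", "covariate"),
                    completeness_formula = ~ 1) {
  weights_type <- match.arg(weights_type)
  stopifnot(inherits(observed, "observed_cohort"))
  estimate <- estimate_ltf_deaths(tracing)

  if (weights_type == "stratum") {
    folded <- fold_tracing(observed, tracing)
    cases <- dplyr::filter(folded, .data$status != "ltf")
    strata <- stratum_ipw_weights(
      c(known_dead = sum(cases$dead10 == 1),
        known_alive = sum(cases$dead10 == 0),
        ltf = tracing$n_ltf),
      estimate
    )
    w <- ifelse(cases$dead10 == 1,
                strata$weight[strata$stratum == "dead"],
                strata$weight[strata$stratum == "alive"])
    details <- list(stratum_table = strata, estimate = estimate,
                    n_unresolved = sum(folded$status == "ltf"))
  } else {
    wtab <- covariate_ipw_weights(observed, tracing, completeness_formula)
    cases <- observed |>
      dplyr::filter(.data$status != "ltf") |>
      dplyr::inner_join(dplyr::select(wtab, "patient_id", "weight"),
                        by = "patient_id")
    cases <- as_observed_cohort(cases)
    w <- cases$weight
    details <- list(weights_table = wtab, estimate = estimate,
                    n_unresolved = sum(observed$status == "ltf") - tracing$n_found)
  }

  d <- scale_covariates(cases)
  tables <- fit_or_tables(d, predictors, weights = w, method = "ipw")
  survival <- survival_at_10(as.data.frame(cases), weights = w)
  weights_tbl <- tibble::tibble(patient_id = cases$patient_id, weight = w)
  new_method_result("ipw", survival, tables,
                    details = c(details, list(weights = weights_tbl)))
}

#' Multiple-imputation analysis
#'
#' Imputes missing covariates and missing vital status with
#' [chained_imputation()], fits every model on each of the M completed
#' datasets, and pools by Rubin's rules. Every model uses the full cohort
#' (N = n).
#'
#' @param observed An `observed_cohort`.
#' @param spec An [imputation_spec()].
#' @param predictors Reporting-scale predictors.
#' @param imp Optionally, a pre-computed `imputation_set` (then `spec` is
#'   ignored).
#' @return A `method_result`; the `imputation_set` is in `details$imp`.
#' @export
run_mice <- function(observed, spec = imputation_spec(),
                     predictors = default_predictors(), imp = NULL) {
  if (is.null(imp)) imp <- chained_imputation(observed, spec)
  tables <- pooled_or_tables(imp$datasets, predictors, method = "mice")
  survival <- survival_at_10(imp)
  new_method_result("mice", survival, tables, details = list(imp = imp))
}

#' Multiple imputation then deletion (sensitivity analysis)
#'
#' Imputes everything as in [run_mice()], then deletes, within each
#' completed dataset, the rows whose *outcome* was imputed (imputed
#' covariates are kept) before fitting and pooling. Model N equals the
#' count of outcome-observed rows.
#'
#' @param imp An `imputation_set`.
#' @param predictors Reporting-scale predictors.
#' @return A `method_result`.
#' @export
mice_then_delete <- function(imp, predictors = default_predictors()) {
  stopifnot(inherits(imp, "imputation_set"))
  keep <- !imp$missing_mask$dead10
  if (!any(keep)) {
    abort("every outcome was imputed; deletion leaves no rows",
          class = "ltfmice_model_error")
  }
  tables <- pooled_or_tables(imp$datasets, predictors, method = "mice_then_delete",
                             mask_keep = keep)
  props <- vapply(imp$datasets, function(d) mean(1 - d$dead10[keep]), numeric(1))
  vars <- vapply(props, function(p) p * (1 - p) / sum(keep), numeric(1))
  pooled <- rubin_pool(matrix(props, ncol = 1, dimnames = list(NULL, "alive")),
                       lapply(vars, function(v) matrix(v)), dfcom = sum(keep) - 1)
  survival <- tibble::tibble(method = "mice_then_delete",
                             estimate = pooled$estimate,
                             conf.low = pooled$conf.low,
                             conf.high = pooled$conf.high,
                             n = sum(keep))
  new_method_result("mice_then_delete", survival, tables,
                    details = list(n_deleted = sum(!keep)))
}

#' Run and compare all analytic methods on one cohort
#'
#' Resolves tracing into the cohort (found-dead become documented deaths,
#' found-alive documented alive — so downstream "LTF" means never found),
#' then runs complete-case, IPW, MICE and MICE-then-delete analyses, plus
#' Kaplan–Meier survival on the pre-tracing cohort (LTF censored at their
#' last visit). A failing method is reported in `$errors` without stopping
#' the others.
#'
#' @param observed An `observed_cohort` (tracing not yet folded).
#' @param tracing A [tracing_result()] with per-patient records.
#' @param spec An [imputation_spec()].
#' @param predictors Reporting-scale predictors.
#' @return An object of class `comparison_report`: `survival` (per-method
#'   ten-year survival with CI), `univariable` and `multivariable` pooled
#'   odds-ratio tables, `n_table`, `errors` and `metadata`.
#' @export
compare_methods <- function(observed, tracing, spec = imputation_spec(),
                            predictors = default_predictors()) {
  stopifnot(inherits(observed, "observed_cohort"))
  folded <- fold_tracing(observed, tracing)
  errors <- list()
  run <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  t0 <- proc.time()[["elapsed"]]
  km <- run("km", {
    ev <- as.integer(observed$status == "dead_documented")
    tm <- ifelse(ev == 1, observed$death_time_years, observed$last_visit_years)
    km_survival(tm, ev)
  })
  cc <- run("cc", run_complete_case(folded, predictors))
  ipw <- run("ipw", run_ipw(observed, tracing, predictors))
  mice <- run("mice", run_mice(folded, spec, predictors))
  micedel <- run("mice_then_delete", {
    if (is.null(mice)) abort("mice failed upstream") else
      mice_then_delete(mice$details$imp, predictors)
  })
  elapsed <- proc.time()[["elapsed"]] - t0

  results <- Filter(Negate(is.null), list(cc = cc, ipw = ipw, mice = mice,
                                          mice_then_delete = micedel))
  survival <- dplyr::bind_rows(c(
    if (!is.null(km)) list(survival_at_10(km)),
    unname(lapply(results, function(r) r$survival))
  ))
  univariable <- dplyr::bind_rows(unname(lapply(results, function(r) r$univariable)))
  multivariable <- dplyr::bind_rows(unname(lapply(results, function(r) r$multivariable)))
  n_table <- multivariable |>
    dplyr::distinct(.data$method, .data$n) |>
    dplyr::rename(n_multivariable = "n")

  structure(
    list(survival = survival,
         univariable = univariable,
         multivariable = multivariable,
         n_table = n_table,
         results = results,
         errors = errors,
         metadata = list(
           n_patients = nrow(observed),
           n_ltf_before_tracing = tracing$n_ltf,
           n_resolved = attr(folded, "n_resolved"),
           imputation_seed = spec$seed,
           M = spec$M,
           elapsed_seconds = elapsed
         )),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> n =", x$metadata$n_patients,
      "| LTF before tracing:", x$metadata$n_ltf_before_tracing,
      "| resolved:", x$metadata$n_resolved, "\n\nTen-year survival:\n")
  print(x$survival)
  cat("\nMultivariable odds ratios:\n")
  print(tidyr::pivot_wider(
    dplyr::select(x$multivariable, "method", "term", "or"),
    names_from = "method", values_from = "or"
  ))
  if (length(x$errors) > 0) {
    cat("\nFailed methods:\n")
    for (nm in names(x$errors)) cat(" ", nm, ":", x$errors[[nm]], "\n")
  }
  invisible(x)
}

#' Write a comparison report as delimited tables plus a JSON manifest
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_comparison_report <- function(report, dir) {
  stopifnot(inherits(report, "comparison_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$survival, file.path(dir, "survival.csv"))
  readr::write_csv(report$univariable, file.path(dir, "or_univariable.csv"))
  readr::write_csv(report$multivariable, file.path(dir, "or_multivariable.csv"))
  readr::write_csv(report$n_table, file.path(dir, "n_table.csv"))
  meta <- report$metadata
  meta$elapsed_seconds <- NULL  # not part of the reproducible payload
  jsonlite::write_json(c(meta, list(errors = report$errors)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
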