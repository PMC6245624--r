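#' Tracing results for patients lost to follow-up
#'
#' Container for the outcome of attempting to trace LTF patients. Either
#' pass per-patient `records` (as produced by [simulate_tracing()]) or the
#' aggregate counts directly — the latter is how published tracing tables
#' enter the pipeline.
#'
#' @param n_ltf Number of LTF patients.
#' @param n_attempted Number attempted (defaults to all).
#' @param n_found Number found.
#' @param n_found_dead Number found who had died.
#' @param records Optional tibble with `patient_id`, `found` (logical) and
#'   `dead_if_found` (0/1, NA when not found); counts are derived from it.
#' @return An object of class `tracing_result`.
#' @examples
#' tracing_result(n_ltf = 156, n_found = 45, n_found_dead = 8)
#' @export
tracing_result <- function(n_ltf = NULL, n_attempted = n_ltf,
                           n_found = NULL, n_found_dead = NULL,
                           records = NULL) {
  if (!is.null(records)) {
    records <- tibble::as_tibble(records)
    stopifnot(all(c("patient_id", "found", "dead_if_found") %in% names(records)))
    n_ltf <- n_ltf %||% nrow(records)
    n_attempted <- nrow(records)
    n_found <- sum(records$found)
    n_found_dead <- sum(records$dead_if_found[records$found], na.rm = TRUE)
  }
  x <- list(n_ltf = as.integer(n_ltf),
            n_attempted = as.integer(n_attempted),
            n_found = as.integer(n_found),
            n_found_dead = as.integer(n_found_dead),
            records = records)
  if (x$n_found > x$n_attempted || x$n_attempted > x$n_ltf ||
      x$n_found_dead > x$n_found || any(unlist(x[1:4]) < 0)) {
    abort("tracing counts must satisfy n_found_dead <= n_found <= n_attempted <= n_ltf",
          class = "ltfmice_tracing_error")
  }
  structure(x, class = "tracing_result")
}

#' @export
print.tracing_result <- function(x, ...) {
  cat("<tracing_result> ", x$n_found, "/", x$n_attempted, " LTF found (",
      round(100 * x$n_found / max(x$n_attempted, 1)), "%); ",
      x$n_found_dead, " found dead\n", sep = "")
  invisible(x)
}

#' Estimate deaths among all LTF patients from tracing
#'
#' Assumes patients found by tracing are representative of all LTF, so the
#' death fraction among those found applies to the whole LTF group. The
#' estimated death count is the half-up-rounded product of the LTF count
#' and that fraction.
#'
#' @param tracing A [tracing_result()] with at least one patient found.
#' @return A tibble of class `ltf_death_estimate` with `n_ltf`,
#'   `death_fraction`, `estimated_deaths` and `estimated_alive`.
#' @examples
#' estimate_ltf_deaths(tracing_result(n_ltf = 156, n_found = 45, n_found_dead = 8))
#' @export
estimate_ltf_deaths <- function(tracing) {
  stopifnot(inherits(tracing, "tracing_result"))
  if (tracing$n_found < 1) {
    abort("tracing uninformative: no LTF patient was found, cannot estimate deaths",
          class = "ltfmice_tracing_error")
  }
  death_fraction <- tracing$n_found_dead / tracing$n_found
  est_dead <- round_half_up(tracing$n_ltf * death_fraction)
  out <- tibble::tibble(
    n_ltf = tracing$n_ltf,
    death_fraction = death_fraction,
    estimated_deaths = est_dead,
    estimated_alive = tracing$n_ltf - est_dead
  )
  class(out) <- c("ltf_death_estimate", class(out))
  out
}

round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Inverse-probability-of-complete-case weights by outcome stratum
#'
#' Computes the probability of having a documented (complete-case) outcome
#' within the dead and alive strata, augmenting the documented counts with
#' the tracing-based estimate of deaths among the LTF, and returns the
#' reciprocal weights. The alive-stratum denominator is documented-alive
#' plus estimated-alive-among-LTF, and symmetrically for deaths.
#'
#' @param status_counts Named vector or list with `known_dead`,
#'   `known_alive` and `ltf` counts (transfers count as known alive).
#' @param estimate An `ltf_death_estimate` for the same `ltf` count.
#' @return A tibble of class `ipw_weights` with one row per stratum:
#'   `stratum`, `n_complete`, `n_estimated`, `p_complete`, `weight`.
#' @examples
#' est <- estimate_ltf_deaths(tracing_result(156, n_found = 45, n_found_dead = 8))
#' stratum_ipw_weights(c(known_dead = 246, known_alive = 482, ltf = 156), est)
#' @export
stratum_ipw_weights <- function(status_counts, estimate) {
  sc <- as.list(status_counts)
  stopifnot(all(c("known_dead", "known_alive", "ltf") %in% names(sc)))
  if (any(unlist(sc[c("known_dead", "known_alive", "ltf")]) < 0)) {
    abort("status counts must be non-negative", class = "ltfmice_ipw_error")
  }
  if (!identical(as.integer(sc$ltf), as.integer(estimate$n_ltf))) {
    abort("estimate was computed for a different LTF count than status_counts$ltf",
          class = "ltfmice_ipw_error")
  }
  est_dead <- estimate$estimated_deaths
  est_alive <- estimate$estimated_alive
  for (stratum in c("dead", "alive")) {
    known <- if (stratum == "dead") sc$known_dead else sc$known_alive
    est <- if (stratum == "dead") est_dead else est_alive
    if (known == 0 && est > 0) {
      abort(paste0("degenerate ", stratum,
                   " stratum: estimated cases but zero complete cases"),
            class = "ltfmice_ipw_error")
    }
  }
  out <- tibble::tibble(
    stratum = c("dead", "alive"),
    n_complete = c(sc$known_dead, sc$known_alive),
    n_estimated = c(est_dead, est_alive),
    p_complete = c(
      if (sc$known_dead + est_dead > 0) sc$known_dead / (sc$known_dead + est_dead) else 1,
      if (sc$known_alive + est_alive > 0) sc$known_alive / (sc$known_alive + est_alive) else 1
    )
  )
  out$weight <- 1 / out$p_complete
  class(out) <- c("ipw_weights", class(out))
  out
}

#' Weighted risk per group and risk ratio
#'
#' Computes the weighted death risk in each group,
#' risk = sum(weight * dead) / sum(weight), and the ratio of each group's
#' risk to the reference (first) group.
#'
#' @param table A data frame of complete cases (one row per patient or per
#'   aggregated cell) with columns `group`, `dead` (0/1), `weight`, and
#'   optionally `n` (cell size, default 1).
#' @param reference Reference group for the ratio; defaults to the first
#'   group in order of appearance.
#' @return A tibble with `group`, `total_weight`, `risk`, `risk_ratio`.
#' @examples
#' worked <- tibble::tibble(
#'   group = c("women", "women", "men", "men"),
#'   dead = c(1, 0, 1, 0), n = c(50, 50, 20, 20),
#'   weight = c(1, 1, 4, 1)
#' )
#' weighted_risk_comparison(worked, reference = "women")
#' @export
weighted_risk_comparison <- function(table, reference = NULL) {
  table <- tibble::as_tibble(table)
  stopifnot(all(c("group", "dead", "weight") %in% names(table)))
  if (!"n" %in% names(table)) table$n <- 1
  out <- table |>
    dplyr::group_by(group = .data$group) |>
    dplyr::summarise(
      total_weight = sum(.data$weight * .data$n),
      risk = sum(.data$weight * .data$n * .data$dead) / sum(.data$weight * .data$n),
      .groups = "drop"
    )
  if (any(out$total_weight <= 0)) {
    abort("undefined risk: a group has zero total weight",
          class = "ltfmice_ipw_error")
  }
  reference <- reference %||% out$group[[1]]
  if (!reference %in% out$group) {
    abort("reference group not present in table", class = "ltfmice_ipw_error")
  }
  ref_risk <- out$risk[out$group == reference]
  out$risk_ratio <- out$risk / ref_risk
  out
}

#' Covariate-conditional inverse-probability-of-complete-case weights
#'
#' Fits a logistic completeness model P(outcome documented | covariates,
#' resolved outcome) over patients with a documented outcome plus LTF
#' patients resolved by tracing, the latter entering with weight `1/f`
#' (`f` = fraction of LTF successfully traced) to represent all LTF. Each
#' complete case then receives weight `1 / p_hat` from this model. With no
#' covariates (`~ 1` plus the outcome) this reduces to the outcome-stratum
#' weights of [stratum_ipw_weights()].
#'
#' @param observed An `observed_cohort` (tracing not yet folded in).
#' @param tracing A [tracing_result()] with per-patient `records`.
#' @param formula RHS-only formula of covariates for the completeness
#'   model; the resolved outcome is always included. Default `~ 1`.
#' @return A tibble of class `ipw_weights` with `patient_id`, `p_complete`
#'   and `weight` for every complete case; the fitted model is attached as
#'   attribute `completeness_fit`.
#' @export
covariate_ipw_weights <- function(observed, tracing, formula = ~ 1) {
  stopifnot(inherits(observed, "observed_cohort"),
            inherits(tracing, "tracing_result"))
  if (is.null(tracing$records)) {
    abort("covariate_ipw_weights needs per-patient tracing records",
          class = "ltfmice_tracing_error")
  }
  if (tracing$n_found < 1) {
    abort("tracing uninformative: no LTF patient was found",
          class = "ltfmice_tracing_error")
  }
  f <- tracing$n_found / tracing$n_attempted

  known <- dplyr::filter(observed, .data$status != "ltf")
  traced <- observed |>
    dplyr::inner_join(dplyr::filter(tracing$records, .data$found),
                      by = "patient_id") |>
    dplyr::mutate(dead10 = as.integer(.data$dead_if_found))

  model_data <- dplyr::bind_rows(
    dplyr::mutate(known, .complete = 1L, .wt = 1),
    dplyr::mutate(traced, .complete = 0L, .wt = 1 / f)
  )
  covar_terms <- attr(stats::terms(formula), "term.labels")
  rhs <- if (length(covar_terms) == 0) {
    "dead10"
  } else {
    # completeness probability is allowed to differ by covariate *within*
    # each outcome stratum (the "unique set of characteristics including
    # predictors and outcomes"), hence the interaction with the outcome
    paste0("(", paste(covar_terms, collapse = " + "), ") * dead10")
  }
  fml <- as.formula(paste(".complete ~", rhs))
  fit <- tryCatch(
    suppressWarnings(glm(fml, family = stats::quasibinomial(),
                         data = model_data, weights = model_data$.wt)),
    error = function(e) abort(paste0("completeness model failed: ",
                                     conditionMessage(e)),
                              class = "ltfmice_model_error")
  )
  if (!fit$converged) {
    abort("completeness model did not converge", class = "ltfmice_model_error")
  }
  p_hat <- predict(fit, newdata = known, type = "response")
  if (any(p_hat < 1e-8)) {
    # separation toward completeness ~ 0 would make weights explode
    abort("completeness model predicts ~0 for some complete cases (separation)",
          class = "ltfmice_model_error")
  }
  out <- tibble::tibble(patient_id = known$patient_id,
                        p_complete = as.numeric(p_hat),
                        weight = 1 / as.numeric(p_hat))
  class(out) <- c("ipw_weights", class(out))
  attr(out, "completeness_fit") <- fit
  attr(out, "trace_fraction") <- f
  out
}

#' Fold tracing results into the observed cohort
#'
#' LTF patients found by tracing have their vital status resolved: found
#' dead becomes `dead_documented`, found alive becomes `alive_in_care`
#' (both flagged `traced`). Patients never found remain `ltf`, so
#' downstream "LTF" means unresolved-after-tracing.
#'
#' @param observed An `observed_cohort`.
#' @param tracing A [tracing_result()] with per-patient `records`.
#' @return The updated `observed_cohort`; the number resolved is attached
#'   as attribute `n_resolved`.
#' @export
fold_tracing <- function(observed, tracing) {
  stopifnot(inherits(observed, "observed_cohort"),
            inherits(tracing, "tracing_result"))
  if (is.null(tracing$records)) {
    abort("fold_tracing needs per-patient tracing records",
          class = "ltfmice_tracing_error")
  }
  found <- dplyr::filter(tracing$records, .data$found)
  idx <- match(found$patient_id, observed$patient_id)
  if (anyNA(idx)) {
    abort("tracing records refer to patient_ids absent from the cohort",
          class = "ltfmice_alignment_error")
  }
  observed$status[idx] <- ifelse(found$dead_if_found == 1,
                                 "dead_documented", "alive_in_care")
  observed$dead10[idx] <- as.integer(found$dead_if_found)
  observed$traced[idx] <- TRUE
  attr(observed, "n_resolved") <- length(idx)
  observed
}

#' Write per-patient weights as a two-column delimited file
#'
#' @param weights An `ipw_weights` tibble with `patient_id` and `weight`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  stopifnot(all(c("patient_id", "weight") %in% names(weights)))
  readr::write_csv(dplyr::select(weights, "patient_id", "weight"), path)
  invisible(path)
}
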