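#' Specification for chained-equation multiple imputation
#'
#' Controls the imputation engine of [chained_imputation()]. The engine
#' imputes missing baseline weight and CD4 by predictive mean matching
#' (PMM) and the missing ten-year vital status by a logistic draw, cycling
#' the three conditional models for a fixed number of iterations per
#' imputation stream. Polynomial terms are imputed passively: the raw
#' variable is imputed and its square (weight) or cube (CD4) recomputed
#' after every update, so the transforms stay functionally consistent.
#'
#' @param M Number of imputations (completed datasets). Default 20.
#' @param k_pmm PMM donor count. Default 5 nearest neighbours.
#' @param n_cycles Chained-equation iterations per imputation before the
#'   dataset is kept. Default 10.
#' @param seed Integer seed for the engine; each imputation stream draws
#'   its own sub-seed so streams are independent yet reproducible.
#' @return An object of class `imputation_spec`.
#' @examples
#' imputation_spec(M = 5, seed = 42)
#' @export
imputation_spec <- function(M = 20, k_pmm = 5, n_cycles = 10, seed = 1L) {
  if (M < 2) abort("M must be >= 2 (single imputation carries no between-imputation variance)",
                   class = "ltfmice_spec_error")
  if (k_pmm < 1) abort("k_pmm must be >= 1", class = "ltfmice_spec_error")
  if (n_cycles < 1) abort("n_cycles must be >= 1", class = "ltfmice_spec_error")
  structure(
    list(M = as.integer(M), k_pmm = as.integer(k_pmm),
         n_cycles = as.integer(n_cycles), seed = as.integer(seed),
         # visit order: ascending missingness (weight 3%, cd4 12%, outcome 12%;
         # the covariate before the outcome at equal rates)
         visit_order = c("weight_kg", "cd4", "dead10")),
    class = "imputation_spec"
  )
}

#' @export
print.imputation_spec <- function(x, ...) {
  cat("<imputation_spec> M =", x$M, "| PMM k =", x$k_pmm,
      "| cycles =", x$n_cycles, "| seed =", x$seed, "\n")
  invisible(x)
}

# Drop collinear / constant columns via pivoted QR (donor design decides
# which columns survive; the missing-row design is subset to match).
align_designs <- function(donor_x, missing_x) {
  donor_x <- as.matrix(donor_x)
  missing_x <- as.matrix(missing_x)
  if (is.null(colnames(donor_x))) {
    colnames(donor_x) <- colnames(missing_x) <- paste0("V", seq_len(ncol(donor_x)))
  }
  q <- qr(donor_x)
  keep <- sort(q$pivot[seq_len(q$rank)])
  list(donor = donor_x[, keep, drop = FALSE],
       missing = missing_x[, keep, drop = FALSE])
}

#' Predictive mean matching for one variable
#'
#' Fits a linear model of the observed target on the donor design, draws
#' coefficients from the approximate posterior (MLE plus a normal
#' perturbation scaled by the estimated coefficient covariance), predicts
#' for the missing rows with the drawn coefficients and for the donors with
#' the posterior-mean fit, and for each missing row copies the observed
#' value of one of the `k` donors with nearest predicted value, chosen
#' uniformly at random. Distance ties are broken by donor index after a
#' seeded shuffle. Imputed values are therefore always members of the
#' observed donor pool.
#'
#' @param donor_y Observed target values (length n_donor).
#' @param donor_x Design matrix for donors (n_donor x p, including
#'   intercept column).
#' @param missing_x Design matrix for rows to impute (n_missing x p).
#' @param k Donor pool size; reduced with a warning when fewer donors exist.
#' @return Numeric vector of imputed values, length `nrow(missing_x)`.
#'   Uses the current RNG state; seed upstream for reproducibility.
#' @export
pmm_impute <- function(donor_y, donor_x, missing_x, k = 5) {
  n_don <- length(donor_y)
  if (n_don == 0) abort("PMM requires at least one donor", class = "ltfmice_impute_error")
  if (nrow(missing_x) == 0) return(numeric(0))
  if (n_don < k) {
    warn(paste0("PMM donor pool (", n_don, ") smaller than k = ", k,
                "; using k = ", n_don))
    k <- n_don
  }
  al <- align_designs(donor_x, missing_x)
  X <- al$donor
  Xm <- al$missing
  fit <- lm.fit(X, donor_y)
  beta <- fit$coefficients
  p <- length(beta)
  rdf <- max(n_don - p, 1)
  sigma2 <- sum(fit$residuals^2) / rdf
  # (X'X)^-1 from the fit's QR (design is pruned to full rank above)
  XtX_inv <- tryCatch(chol2inv(qr.R(fit$qr)), error = function(e) solve(crossprod(X)))
  V <- sigma2 * XtX_inv
  beta_star <- beta + drop(t(chol(pd_jitter(V))) %*% rnorm(p))

  pred_mis <- drop(Xm %*% beta_star)
  pred_don <- drop(X %*% beta)

  shuffle <- sample.int(n_don)
  vapply(pred_mis, function(ph) {
    d <- abs(pred_don - ph)
    pool <- order(d, shuffle)[seq_len(k)]
    donor_y[pool[sample.int(k, 1)]]
  }, numeric(1))
}

# Nudges a covariance matrix to positive definiteness for the Cholesky draw.
pd_jitter <- function(V, eps = 1e-10) {
  V <- (V + t(V)) / 2
  diag(V) <- diag(V) + eps * max(diag(V), 1)
  V
}

#' Impute a missing binary outcome by a posterior-draw logistic model
#'
#' Fits a logistic regression of the observed outcome on the donor design,
#' perturbs the coefficients by a draw from their estimated normal
#' posterior, and samples each missing outcome Bernoulli at its drawn
#' predicted probability.
#'
#' @param donor_y Observed 0/1 outcomes.
#' @param donor_x Design matrix for rows with observed outcome.
#' @param missing_x Design matrix for rows to impute.
#' @return Integer vector of 0/1 draws. Uses the current RNG state.
#' @export
impute_binary_outcome <- function(donor_y, donor_x, missing_x) {
  if (length(unique(donor_y)) < 2) {
    abort("observed outcome has a single class; logistic imputation model undefined",
          class = "ltfmice_impute_error")
  }
  if (nrow(missing_x) == 0) return(integer(0))
  al <- align_designs(donor_x, missing_x)
  X <- al$donor
  Xm <- al$missing
  fit <- suppressWarnings(glm.fit(X, donor_y, family = binomial()))
  beta <- fit$coefficients
  if (!fit$converged || any(!is.finite(beta)) || any(abs(beta) > 25)) {
    abort(paste0("logistic imputation model unstable (possible separation); ",
                 "max |coef| = ", signif(max(abs(beta)), 3)),
          class = "ltfmice_impute_error")
  }
  w <- fit$weights
  V <- tryCatch(chol2inv(chol(crossprod(X * sqrt(w)))),
                error = function(e) abort("singular information matrix in outcome imputation",
                                          class = "ltfmice_impute_error"))
  beta_star <- beta + drop(t(chol(pd_jitter(V))) %*% rnorm(length(beta)))
  p_hat <- plogis(drop(Xm %*% beta_star))
  rbinom(nrow(Xm), 1, p_hat)
}

# Conditional-model designs on the analysis scale. Each target's own
# transform is excluded (recomputed passively); all other analysis
# variables, including the partner variable's polynomial term, predict it.
mice_design <- function(frame, target) {
  base <- cbind(
    intercept = 1,
    female = frame$female,
    age10 = frame$age10,
    residence_pap = frame$residence_pap,
    severe_poverty = frame$severe_poverty,
    who_stage_advanced = frame$who_stage_advanced,
    tb_baseline = frame$tb_baseline
  )
  weight10 <- frame$weight_kg / 10
  cd4_100 <- frame$cd4 / 100
  weight_terms <- cbind(weight10 = weight10, weight10_sq = weight10^2)
  cd4_terms <- cbind(cd4_100 = cd4_100, cd4_100_cu = cd4_100^3)
  switch(target,
    weight_kg = cbind(base, cd4_terms, dead10 = frame$dead10),
    cd4 = cbind(base, weight_terms, dead10 = frame$dead10),
    dead10 = cbind(base, weight_terms, cd4_terms)
  )
}

#' Multiple imputation by chained equations for an observed cohort
#'
#' Runs `M` independent imputation streams. Each stream initialises every
#' missing cell by a random draw from the variable's observed values, then
#' cycles the conditional models in a fixed visit order (weight, CD4, vital
#' status) for `n_cycles` iterations, recomputing the passive polynomial
#' terms after every variable update. Missing weight and CD4 are imputed by
#' [pmm_impute()]; missing vital status (LTF patients) by
#' [impute_binary_outcome()]. Transferred patients enter with outcome fixed
#' alive; documented deaths with outcome fixed dead.
#'
#' @param observed An `observed_cohort` (fold tracing first if tracing
#'   results should count as documented).
#' @param spec An [imputation_spec()].
#' @return An object of class `imputation_set`: `datasets` (list of `M`
#'   completed cohort tibbles, no missing analysis values), `chain_history`
#'   (per imputation x iteration x variable mean/SD of the imputed cells),
#'   `missing_mask` (logical tibble marking originally missing cells),
#'   `spec`, and `seeds` (the per-stream seed ledger).
#' @examples
#' cfg <- generator_config(n_patients = 150, seed = 3)
#' obs <- apply_missingness(generate_cohort(cfg), cfg)
#' imp <- chained_imputation(obs, imputation_spec(M = 3, n_cycles = 3, seed = 9))
#' length(imp$datasets)
#' @export
chained_imputation <- function(observed, spec = imputation_spec()) {
  stopifnot(inherits(observed, "observed_cohort"),
            inherits(spec, "imputation_spec"))
  n <- nrow(observed)

  mask <- tibble::tibble(
    weight_kg = is.na(observed$weight_kg),
    cd4 = is.na(observed$cd4),
    dead10 = is.na(observed$dead10)
  )
  for (v in names(mask)) {
    frac <- mean(mask[[v]])
    if (frac >= 0.5) {
      abort(paste0(v, " is ", round(100 * frac), "% missing; chained imputation refused"),
            class = "ltfmice_impute_error")
    }
    if (frac > 0.3) {
      warn(paste0(v, " is ", round(100 * frac),
                  "% missing; imputation is most reliable below 30%"))
    }
  }
  if (anyNA(observed$female) || anyNA(observed$age_years)) {
    abort("fully-observed covariates contain NA; only weight, CD4 and vital status may be missing",
          class = "ltfmice_impute_error")
  }

  set.seed(spec$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, spec$M)

  base_frame <- tibble::tibble(
    female = observed$female,
    age10 = observed$age_years / 10,
    residence_pap = observed$residence_pap,
    severe_poverty = observed$severe_poverty,
    who_stage_advanced = observed$who_stage_advanced,
    tb_baseline = observed$tb_baseline,
    weight_kg = observed$weight_kg,
    cd4 = observed$cd4,
    dead10 = as.numeric(observed$dead10)
  )
  imputable <- spec$visit_order[c(any(mask$weight_kg), any(mask$cd4), any(mask$dead10))]

  datasets <- vector("list", spec$M)
  history <- vector("list", spec$M)

  for (m in seq_len(spec$M)) {
    set.seed(seeds[m])
    frame <- base_frame

    # initialise from observed marginals
    if (any(mask$weight_kg)) {
      frame$weight_kg[mask$weight_kg] <-
        sample(frame$weight_kg[!mask$weight_kg], sum(mask$weight_kg), replace = TRUE)
    }
    if (any(mask$cd4)) {
      frame$cd4[mask$cd4] <-
        sample(frame$cd4[!mask$cd4], sum(mask$cd4), replace = TRUE)
    }
    if (any(mask$dead10)) {
      frame$dead10[mask$dead10] <-
        sample(frame$dead10[!mask$dead10], sum(mask$dead10), replace = TRUE)
    }

    hist_m <- list()
    for (it in seq_len(spec$n_cycles)) {
      for (v in imputable) {
        mk <- mask[[v]]
        X <- mice_design(frame, v)
        if (v == "dead10") {
          frame$dead10[mk] <- as.numeric(
            impute_binary_outcome(frame$dead10[!mk], X[!mk, , drop = FALSE],
                                  X[mk, , drop = FALSE])
          )
        } else {
          frame[[v]][mk] <- pmm_impute(frame[[v]][!mk],
                                       X[!mk, , drop = FALSE],
                                       X[mk, , drop = FALSE],
                                       k = spec$k_pmm)
        }
        imp_vals <- frame[[v]][mk]
        hist_m[[length(hist_m) + 1]] <- tibble::tibble(
          imputation = m, iteration = it, variable = v,
          mean = mean(imp_vals),
          sd = if (length(imp_vals) > 1) sd(imp_vals) else 0
        )
      }
    }

    # only the originally missing cells are replaced, so observed cells
    # stay bit-identical across all M datasets
    completed <- observed
    completed$weight_kg[mask$weight_kg] <- frame$weight_kg[mask$weight_kg]
    completed$cd4[mask$cd4] <- frame$cd4[mask$cd4]
    completed$dead10[mask$dead10] <- as.integer(frame$dead10[mask$dead10])
    attr(completed, "imputation") <- m
    datasets[[m]] <- completed
    history[[m]] <- dplyr::bind_rows(hist_m)
  }

  structure(
    list(datasets = datasets,
         chain_history = dplyr::bind_rows(history),
         missing_mask = mask,
         spec = spec,
         seeds = seeds,
         n = n),
    class = "imputation_set"
  )
}

#' @export
print.imputation_set <- function(x, ...) {
  cat("<imputation_set> M =", length(x$datasets), "completed datasets of n =",
      x$n, "\n  originally missing:",
      paste(names(x$missing_mask), colSums(x$missing_mask), sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Numeric diagnostics for an imputation set
#'
#' Summarises imputed against observed values (median and IQR per
#' variable), the death proportion among imputed outcomes, and the
#' per-iteration chain means with a no-trend statistic: the slope of a
#' regression of chain mean on iteration (pooled over streams) with its
#' p-value. A healthy chain shows imputed distributions comparable to the
#' observed ones and no significant trend.
#'
#' @param imp An `imputation_set`.
#' @param observed The `observed_cohort` it was built from.
#' @return A list of class `diagnostics_report` with tibbles
#'   `value_summary`, `outcome_summary`, `chain_trend` and `chain_history`.
#' @export
imputation_diagnostics <- function(imp, observed) {
  stopifnot(inherits(imp, "imputation_set"))
  mask <- imp$missing_mask

  summarise_var <- function(var) {
    obs_vals <- observed[[var]][!mask[[var]]]
    imp_vals <- unlist(lapply(imp$datasets, function(d) d[[var]][mask[[var]]]))
    if (length(imp_vals) == 0) return(NULL)
    tibble::tibble(
      variable = var,
      n_missing = sum(mask[[var]]),
      observed_median = median(obs_vals),
      observed_q1 = quantile(obs_vals, 0.25, names = FALSE),
      observed_q3 = quantile(obs_vals, 0.75, names = FALSE),
      imputed_median = median(imp_vals),
      imputed_q1 = quantile(imp_vals, 0.25, names = FALSE),
      imputed_q3 = quantile(imp_vals, 0.75, names = FALSE)
    )
  }
  value_summary <- dplyr::bind_rows(lapply(c("weight_kg", "cd4"), summarise_var))

  outcome_summary <- if (any(mask$dead10)) {
    tibble::tibble(
      n_imputed_outcomes = sum(mask$dead10),
      imputed_death_proportion = mean(unlist(
        lapply(imp$datasets, function(d) d$dead10[mask$dead10])
      )),
      observed_death_proportion = mean(observed$dead10[!mask$dead10])
    )
  } else {
    tibble::tibble(n_imputed_outcomes = integer(0),
                   imputed_death_proportion = numeric(0),
                   observed_death_proportion = numeric(0))
  }

  chain_trend <- if (nrow(imp$chain_history) > 0 && imp$spec$n_cycles > 1) {
    imp$chain_history |>
      dplyr::group_by(variable = .data$variable) |>
      dplyr::group_modify(function(d, key) {
        fit <- stats::lm(mean ~ iteration, data = d)
        sm <- summary(fit)$coefficients
        tibble::tibble(slope = sm["iteration", "Estimate"],
                       p_value = sm["iteration", "Pr(>|t|)"])
      }) |>
      dplyr::ungroup()
  } else {
    tibble::tibble(variable = character(0), slope = numeric(0), p_value = numeric(0))
  }

  structure(list(value_summary = value_summary,
                 outcome_summary = outcome_summary,
                 chain_trend = chain_trend,
                 chain_history = imp$chain_history),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("<diagnostics_report>\n")
  if (nrow(x$value_summary) > 0) print(x$value_summary) else
    cat("  no imputed continuous values\n")
  if (nrow(x$outcome_summary) > 0) print(x$outcome_summary)
  if (nrow(x$chain_trend) > 0) {
    cat("  chain trend (slope of chain mean on iteration):\n")
    print(x$chain_trend)
  }
  invisible(x)
}

#' Serialise an imputation set to delimited files plus a manifest
#'
#' Writes one CSV per completed dataset (`imputation_01.csv`, ...) and a
#' JSON manifest with the spec, per-stream seeds and chain history.
#'
#' @param imp An `imputation_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_imputations <- function(imp, dir) {
  stopifnot(inherits(imp, "imputation_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (m in seq_along(imp$datasets)) {
    readr::write_csv(imp$datasets[[m]],
                     file.path(dir, sprintf("imputation_%02d.csv", m)), na = "")
  }
  manifest <- list(
    M = imp$spec$M, k_pmm = imp$spec$k_pmm, n_cycles = imp$spec$n_cycles,
    seed = imp$spec$seed, stream_seeds = imp$seeds,
    n = imp$n,
    n_missing = as.list(colSums(imp$missing_mask)),
    chain_history = imp$chain_history
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
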