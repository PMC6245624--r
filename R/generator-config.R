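#' Configuration for the synthetic cohort generator
#'
#' Builds the full parameter set that drives [generate_cohort()],
#' [apply_missingness()] and [simulate_tracing()]. The defaults emulate a
#' 910-adult HIV treatment cohort followed for ten years: roughly 30% true
#' ten-year mortality, 17% of patients lost to follow-up (LTF) before any
#' tracing, 8% documented transfers (transfers occur only among truly alive
#' patients and are treated as alive at ten years), baseline missingness of
#' 3% for weight and 12% for CD4, and a tracing operation that finds about
#' 29% of LTF patients.
#'
#' The loss-to-follow-up mechanism is a logistic model on baseline
#' covariates. With `ltf_model["true_dead10"] = 0` (the default) loss is
#' missing at random (MAR) given covariates — the assumption under which
#' chained-equation imputation is valid. Setting that coefficient away from
#' zero makes loss depend on the unobserved vital status itself (MNAR),
#' which is the switch used in the package's bias experiments.
#'
#' @param n_patients Cohort size. Default 910.
#' @param covariate_params Named list of marginal-distribution parameters;
#'   see the default value for the full set. Weight is normal within sex
#'   (medians 56 kg men / 49 kg women), CD4 is lognormal with median 131
#'   cells/uL truncated to `[0, 1500]`, age is normal truncated to 13+ years.
#' @param outcome_model Named numeric vector of log-odds coefficients for
#'   death by ten years, on the reporting scale (age per 10 years, weight
#'   per 10 kg, CD4 per 100 cells/uL), plus an `intercept`.
#' @param ltf_model Named numeric vector of log-odds coefficients for
#'   becoming LTF, same scale, plus `intercept` and a `true_dead10`
#'   coefficient (0 = MAR).
#' @param transfer_prob Probability that a truly alive, non-LTF patient has
#'   a documented transfer (transfers are assumed alive at ten years).
#' @param cov_missing_rates Named vector of baseline covariate missingness
#'   probabilities (`weight_kg`, `cd4`), applied completely at random.
#' @param tracing_params List with `success_prob` (marginal probability that
#'   an LTF patient is found) and `recency_slope` (log-odds increase in
#'   success per year of later last visit; 0 keeps success homogeneous).
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#'
#' @return An object of class `generator_config` (a validated named list).
#' @examples
#' cfg <- generator_config(n_patients = 200, seed = 1)
#' cohort <- generate_cohort(cfg)
#' @export
generator_config <- function(n_patients = 910,
                             covariate_params = list(),
                             outcome_model = NULL,
                             ltf_model = NULL,
                             transfer_prob = 0.135,
                             cov_missing_rates = c(weight_kg = 0.03, cd4 = 0.12),
                             tracing_params = list(success_prob = 0.29,
                                                   recency_slope = 0),
                             seed = 1L) {
  cov_defaults <- list(
    p_female = 0.55,
    age_mean = 37, age_sd = 10, age_min = 13, age_max = 80,
    p_severe_poverty = 0.40,
    p_residence_pap = 0.60,
    weight_mean_male = 56, weight_mean_female = 49,
    weight_sd = 9, weight_min = 30, weight_max = 130,
    cd4_meanlog = log(131), cd4_sdlog = 1.0, cd4_max = 1500,
    p_who_advanced = 0.45,
    p_tb = 0.15
  )
  covariate_params <- modifyList(cov_defaults, covariate_params)

  # Default effect sizes follow the multivariable mortality model the
  # package is designed to recover (OR scale: female 0.62, age 1.37/10yr,
  # residence 1.18, poverty 1.80, CD4 0.91/100 cells, weight 0.66/10kg,
  # WHO stage 1.76, TB 1.61). Intercepts are calibrated once by large-n
  # Monte Carlo so the marginals hit ~30% mortality and ~17% LTF.
  out_defaults <- c(
    intercept = -0.138,
    female = log(0.62), age10 = log(1.37), residence_pap = log(1.18),
    severe_poverty = log(1.80), cd4_100 = log(0.91), weight10 = log(0.66),
    who_stage_advanced = log(1.76), tb_baseline = log(1.61)
  )
  if (is.null(outcome_model)) outcome_model <- out_defaults
  outcome_model <- fill_coefs(outcome_model, out_defaults)

  ltf_defaults <- c(
    intercept = -0.653,
    female = 0, age10 = -0.10, residence_pap = -0.20,
    severe_poverty = 0.30, cd4_100 = -0.10, weight10 = -0.10,
    who_stage_advanced = 0.30, tb_baseline = 0,
    true_dead10 = 0
  )
  if (is.null(ltf_model)) ltf_model <- ltf_defaults
  ltf_model <- fill_coefs(ltf_model, ltf_defaults)

  cfg <- structure(
    list(n_patients = n_patients,
         covariate_params = covariate_params,
         outcome_model = outcome_model,
         ltf_model = ltf_model,
         transfer_prob = transfer_prob,
         cov_missing_rates = cov_missing_rates,
         tracing_params = modifyList(list(success_prob = 0.29, recency_slope = 0),
                                     tracing_params),
         seed = as.integer(seed)),
    class = "generator_config"
  )
  validate_generator_config(cfg)
}

# Merge user-supplied coefficients over the default vector; unknown names error.
fill_coefs <- function(x, defaults) {
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    abort("model coefficient vectors must be fully named")
  }
  extra <- setdiff(names(x), names(defaults))
  if (length(extra) > 0) {
    abort(paste0("unknown coefficient(s): ", paste(extra, collapse = ", ")))
  }
  defaults[names(x)] <- x
  defaults
}

validate_generator_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      is.na(cfg$n_patients) || cfg$n_patients < 1) {
    abort("n_patients must be a single integer >= 1", class = "ltfmice_config_error")
  }
  probs <- c(cfg$transfer_prob, cfg$cov_missing_rates,
             cfg$tracing_params$success_prob,
             unlist(cfg$covariate_params[grep("^p_", names(cfg$covariate_params))]))
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("all probabilities must lie in [0, 1]", class = "ltfmice_config_error")
  }
  for (nm in c("weight_kg", "cd4")) {
    if (!nm %in% names(cfg$cov_missing_rates)) {
      abort(paste0("cov_missing_rates must name ", nm), class = "ltfmice_config_error")
    }
  }
  cfg$n_patients <- as.integer(cfg$n_patients)
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat("  n_patients:", x$n_patients, " seed:", x$seed, "\n")
  cat("  transfer_prob:", x$transfer_prob,
      " missing:", paste(names(x$cov_missing_rates), x$cov_missing_rates,
                         sep = "=", collapse = " "), "\n")
  cat("  tracing success:", x$tracing_params$success_prob,
      " recency slope:", x$tracing_params$recency_slope, "\n")
  cat("  MNAR coefficient on true outcome:", x$ltf_model[["true_dead10"]], "\n")
  invisible(x)
}

#' Read or write a generator configuration as JSON
#'
#' @param cfg A `generator_config`.
#' @param path File path.
#' @return `read_generator_config()` returns a `generator_config`;
#'   `write_generator_config()` returns `path` invisibly.
#' @export
write_generator_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "generator_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  generator_config(
    n_patients = raw$n_patients,
    covariate_params = as.list(raw$covariate_params),
    outcome_model = unlist(raw$outcome_model),
    ltf_model = unlist(raw$ltf_model),
    transfer_prob = raw$transfer_prob,
    cov_missing_rates = unlist(raw$cov_missing_rates),
    tracing_params = as.list(raw$tracing_params),
    seed = raw$seed
  )
}

# Short stable hash of a config for run logs (no external digest dependency).
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}
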