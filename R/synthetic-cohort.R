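#' Generate a synthetic cohort with known ground truth
#'
#' Draws baseline covariates from the configured marginals and the true
#' ten-year vital status from the logistic outcome model, giving every
#' downstream estimator a cohort whose answer is known. Death times are
#' drawn with an early-weighted profile (mortality after treatment
#' initiation is front-loaded); patients who die have their last clinic
#' visit at the death time, survivors at ten years.
#'
#' @param config A [generator_config()].
#' @return A tibble of class `cohort_table`: one row per patient with
#'   `patient_id`, covariates (`female`, `age_years`, `severe_poverty`,
#'   `residence_pap`, `weight_kg`, `cd4`, `who_stage_advanced`,
#'   `tb_baseline`), `true_dead10`, `death_time_years` (NA if alive) and
#'   `last_visit_years`.
#' @examples
#' cohort <- generate_cohort(generator_config(n_patients = 100, seed = 7))
#' mean(cohort$true_dead10)
#' @export
generate_cohort <- function(config) {
  config <- validate_generator_config(config)
  n <- config$n_patients
  cp <- config$covariate_params

  set.seed(config$seed)
  female <- rbinom(n, 1, cp$p_female)
  age_years <- rtrunc_norm(n, cp$age_mean, cp$age_sd, cp$age_min, cp$age_max)
  severe_poverty <- rbinom(n, 1, cp$p_severe_poverty)
  residence_pap <- rbinom(n, 1, cp$p_residence_pap)
  weight_mean <- ifelse(female == 1, cp$weight_mean_female, cp$weight_mean_male)
  weight_kg <- rtrunc_norm(n, weight_mean, cp$weight_sd, cp$weight_min, cp$weight_max)
  cd4 <- rtrunc_lnorm(n, cp$cd4_meanlog, cp$cd4_sdlog, cp$cd4_max)
  who_stage_advanced <- rbinom(n, 1, cp$p_who_advanced)
  tb_baseline <- rbinom(n, 1, cp$p_tb)

  covars <- tibble::tibble(
    patient_id = seq_len(n),
    female, age_years, severe_poverty, residence_pap,
    weight_kg, cd4, who_stage_advanced, tb_baseline
  )

  eta <- model_linear_predictor(covars, config$outcome_model)
  true_dead10 <- rbinom(n, 1, plogis(eta))

  # Death times on (0, 10]: Beta(0.8, 1.4) scaled to 10 years, putting the
  # bulk of deaths in the first years on treatment.
  death_time_years <- rep(NA_real_, n)
  ndead <- sum(true_dead10)
  if (ndead > 0) {
    death_time_years[true_dead10 == 1] <- 10 * stats::rbeta(ndead, 0.8, 1.4)
  }
  last_visit_years <- ifelse(true_dead10 == 1, death_time_years, 10)

  out <- dplyr::mutate(covars,
                       true_dead10 = true_dead10,
                       death_time_years = death_time_years,
                       last_visit_years = last_visit_years)
  class(out) <- c("cohort_table", class(out))
  attr(out, "config_hash") <- config_hash(config)
  out
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

rtrunc_lnorm <- function(n, meanlog, sdlog, hi) {
  x <- rlnorm(n, meanlog, sdlog)
  bad <- which(x > hi)
  while (length(bad) > 0) {
    x[bad] <- rlnorm(length(bad), meanlog, sdlog)
    bad <- bad[x[bad] > hi]
  }
  x
}

# Linear predictor on the reporting scale (age/10, weight/10, cd4/100) for a
# named coefficient vector with an `intercept` entry.
model_linear_predictor <- function(data, coefs) {
  design <- cbind(
    intercept = 1,
    female = data$female,
    age10 = data$age_years / 10,
    residence_pap = data$residence_pap,
    severe_poverty = data$severe_poverty,
    cd4_100 = data$cd4 / 100,
    weight10 = data$weight_kg / 10,
    who_stage_advanced = data$who_stage_advanced,
    tb_baseline = data$tb_baseline
  )
  if ("true_dead10" %in% names(coefs) && coefs[["true_dead10"]] != 0) {
    design <- cbind(design, true_dead10 = data$true_dead10)
  }
  used <- intersect(colnames(design), names(coefs))
  drop(design[, used, drop = FALSE] %*% coefs[used])
}

#' Apply the observation process: status categories and covariate missingness
#'
#' Turns the ground-truth cohort into the analyst's view. Each patient is
#' assigned an observed ten-year status: truly dead patients become
#' `dead_documented` unless lost (then `ltf`, an undocumented death); truly
#' alive patients become `ltf` with the same covariate-driven probability,
#' otherwise `transferred` with the configured probability (transfers are
#' assumed alive at ten years), otherwise `alive_in_care`. Loss follows the
#' logistic `ltf_model`; with its `true_dead10` coefficient at 0 the
#' mechanism is MAR given covariates. Baseline weight and CD4 are then
#' masked completely at random at the configured rates. LTF patients get a
#' last visit drawn uniformly over their time under follow-up.
#'
#' @param cohort A `cohort_table` from [generate_cohort()].
#' @param config The same [generator_config()].
#' @return A tibble of class `observed_cohort` with `status`
#'   (`alive_in_care` / `dead_documented` / `transferred` / `ltf`),
#'   observable covariates (weight/CD4 possibly NA), `dead10` (NA for LTF),
#'   `death_time_years` (documented deaths only), `last_visit_years`, and a
#'   `traced` flag (all FALSE until tracing results are folded in).
#' @export
apply_missingness <- function(cohort, config) {
  stopifnot(inherits(cohort, "cohort_table"))
  config <- validate_generator_config(config)
  n <- nrow(cohort)
  set.seed(config$seed + 1000003L)

  p_ltf <- plogis(model_linear_predictor(cohort, config$ltf_model))
  is_ltf <- rbinom(n, 1, p_ltf) == 1
  is_transfer <- !is_ltf & cohort$true_dead10 == 0 &
    rbinom(n, 1, config$transfer_prob) == 1

  status <- dplyr::case_when(
    is_ltf ~ "ltf",
    cohort$true_dead10 == 1 ~ "dead_documented",
    is_transfer ~ "transferred",
    TRUE ~ "alive_in_care"
  )
  status <- factor(status, levels = status_levels())

  # Last visit: documented deaths keep the death time; LTF patients stop
  # attending at a uniform point of their follow-up; others reach 10 years.
  u <- runif(n)
  last_visit <- dplyr::case_when(
    status == "ltf" & cohort$true_dead10 == 1 ~ u * cohort$death_time_years,
    status == "ltf" ~ u * 10,
    status == "dead_documented" ~ cohort$death_time_years,
    TRUE ~ 10
  )

  weight_obs <- cohort$weight_kg
  cd4_obs <- cohort$cd4
  weight_obs[runif(n) < config$cov_missing_rates[["weight_kg"]]] <- NA_real_
  cd4_obs[runif(n) < config$cov_missing_rates[["cd4"]]] <- NA_real_

  out <- tibble::tibble(
    patient_id = cohort$patient_id,
    female = cohort$female,
    age_years = cohort$age_years,
    severe_poverty = cohort$severe_poverty,
    residence_pap = cohort$residence_pap,
    weight_kg = weight_obs,
    cd4 = cd4_obs,
    who_stage_advanced = cohort$who_stage_advanced,
    tb_baseline = cohort$tb_baseline,
    status = status,
    dead10 = dplyr::case_when(status == "dead_documented" ~ 1L,
                              status == "ltf" ~ NA_integer_,
                              TRUE ~ 0L),
    death_time_years = ifelse(status == "dead_documented",
                              cohort$death_time_years, NA_real_),
    last_visit_years = last_visit,
    traced = FALSE
  )
  class(out) <- c("observed_cohort", class(out))
  attr(out, "config_hash") <- config_hash(config)
  out
}

status_levels <- function() {
  c("alive_in_care", "dead_documented", "transferred", "ltf")
}

#' Validate a tibble as an observed cohort
#'
#' Checks the delimited-file schema used throughout the package and attaches
#' the `observed_cohort` class, so externally assembled tables (e.g. read
#' with [read_cohort()] or built from published counts) can enter the
#' pipeline.
#'
#' @param data A data frame with the `observed_cohort` columns.
#' @return The validated `observed_cohort` tibble.
#' @export
as_observed_cohort <- function(data) {
  data <- tibble::as_tibble(data)
  needed <- c("patient_id", "female", "age_years", "severe_poverty",
              "residence_pap", "weight_kg", "cd4", "who_stage_advanced",
              "tb_baseline", "status", "last_visit_years")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("observed cohort lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "ltfmice_schema_error")
  }
  data$status <- factor(as.character(data$status), levels = status_levels())
  if (anyNA(data$status)) {
    abort("status must be one of alive_in_care/dead_documented/transferred/ltf",
          class = "ltfmice_schema_error")
  }
  if (!"dead10" %in% names(data)) {
    data$dead10 <- dplyr::case_when(data$status == "dead_documented" ~ 1L,
                                    data$status == "ltf" ~ NA_integer_,
                                    TRUE ~ 0L)
  }
  if (!"death_time_years" %in% names(data)) data$death_time_years <- NA_real_
  if (!"traced" %in% names(data)) data$traced <- FALSE
  if (!inherits(data, "observed_cohort")) {
    class(data) <- c("observed_cohort", class(data))
  }
  data
}

#' Simulate active tracing of patients lost to follow-up
#'
#' Every LTF patient is attempted; each is found with the configured success
#' probability (optionally higher for more recently lost patients, on the
#' log-odds scale), and found patients report their true vital status.
#'
#' @param observed An `observed_cohort`.
#' @param truth The matching `cohort_table` (same `patient_id`s).
#' @param config The [generator_config()].
#' @return A [tracing_result()].
#' @export
simulate_tracing <- function(observed, truth, config) {
  stopifnot(inherits(observed, "observed_cohort"))
  config <- validate_generator_config(config)
  if (!identical(observed$patient_id, truth$patient_id)) {
    abort("observed and truth tables must carry identical patient_id order",
          class = "ltfmice_alignment_error")
  }
  set.seed(config$seed + 2000003L)
  ltf_idx <- which(observed$status == "ltf")
  tp <- config$tracing_params
  eta <- qlogis(min(max(tp$success_prob, 1e-12), 1 - 1e-12)) +
    tp$recency_slope * (observed$last_visit_years[ltf_idx] - 5)
  p_found <- plogis(eta)
  if (tp$success_prob == 0) p_found <- rep(0, length(ltf_idx))
  if (tp$success_prob == 1 && tp$recency_slope == 0) p_found <- rep(1, length(ltf_idx))
  found <- rbinom(length(ltf_idx), 1, p_found) == 1

  records <- tibble::tibble(
    patient_id = observed$patient_id[ltf_idx],
    found = found,
    dead_if_found = ifelse(found, truth$true_dead10[ltf_idx], NA_integer_)
  )
  tracing_result(records = records)
}

#' Read or write cohort tables as delimited text
#'
#' Cohorts are exchanged as comma-delimited files with a header row and
#' empty fields for missing values.
#'
#' @param data A `cohort_table` or `observed_cohort`.
#' @param path File path.
#' @return `read_cohort()` returns an `observed_cohort` (or plain tibble if
#'   the status column is absent); `write_cohort()` returns `path`
#'   invisibly.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(data, path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  data <- readr::read_csv(path, na = "", show_col_types = FALSE)
  if ("status" %in% names(data)) as_observed_cohort(data) else data
}
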