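# Independent oracles and shared fixtures for the test suite.
# These deliberately avoid the package's own code paths (and glm/survfit)
# so that implementation and check stay on separate routes.

# Closed-form weighted logistic MLE for a 2x2 table.
# Cells: counts/weights for exposure x in {0,1} and outcome y in {0,1}.
# The saturated MLE fits each exposure group's weighted death odds exactly:
#   b0 = log odds in x = 0, b1 = log OR between groups.
logistic_2x2_oracle <- function(w00, w01, w10, w11) {
  # wxy = total weight with exposure x and outcome y; all must be > 0
  stopifnot(w00 > 0, w01 > 0, w10 > 0, w11 > 0)
  b0 <- log(w01 / w00)
  b1 <- log(w11 / w10) - b0
  c(intercept = b0, slope = b1)
}

# Product-limit survival by explicit risk-set enumeration. At tied times
# deaths are processed while same-time censorings are still in the risk set.
km_oracle <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = numeric(0), surv = numeric(0))
  for (t in ut) {
    n_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n_risk)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}
km_oracle_at <- function(times, events, t) {
  o <- km_oracle(times, events)
  if (nrow(o) == 0 || all(o$time > t)) return(1)
  o$surv[max(which(o$time <= t))]
}

# The published worked example: 100 women (50 dead, 50 alive, all complete),
# 100 men (20 dead and 20 alive complete, 60 LTF all traced and found dead).
worked_example_cohort <- function() {
  n <- 200
  female <- rep(c(1, 0), each = 100)
  dead_true <- c(rep(1, 50), rep(0, 50),        # women
                 rep(1, 20), rep(0, 20), rep(1, 60))  # men (last 60 LTF, dead)
  status <- c(rep("dead_documented", 50), rep("alive_in_care", 50),
              rep("dead_documented", 20), rep("alive_in_care", 20),
              rep("ltf", 60))
  tibble::tibble(
    patient_id = seq_len(n),
    female = female,
    age_years = 35,
    severe_poverty = 0L,
    residence_pap = 0L,
    weight_kg = 55,
    cd4 = 150,
    who_stage_advanced = 0L,
    tb_baseline = 0L,
    status = status,
    last_visit_years = ifelse(status == "ltf", 5, 10),
    true_dead10 = dead_true
  ) |> as_observed_cohort()
}

worked_example_tracing <- function(cohort) {
  ltf_ids <- cohort$patient_id[cohort$status == "ltf"]
  tracing_result(records = tibble::tibble(
    patient_id = ltf_ids, found = TRUE, dead_if_found = 1L
  ))
}

# Small default cohort shared by several tests.
small_cohort <- function(n = 400, seed = 42, ...) {
  cfg <- generator_config(n_patients = n, seed = seed, ...)
  truth <- generate_cohort(cfg)
  obs <- apply_missingness(truth, cfg)
  list(cfg = cfg, truth = truth, obs = obs,
       tracing = simulate_tracing(obs, truth, cfg))
}

# Paper-shaped observed cohort with exact status and tracing counts,
# assembled from generator ground truth: 156 LTF of whom 45 are traced
# (8 found dead, 37 found alive), 71 transfers, the rest documented.
paper_shaped_cohort <- function(seed = 1) {
  cfg <- generator_config(n_patients = 910, seed = seed)
  truth <- generate_cohort(cfg)
  dead_ids <- truth$patient_id[truth$true_dead10 == 1]
  alive_ids <- truth$patient_id[truth$true_dead10 == 0]
  # need 35 truly dead among the LTF (8 traced dead + 27 unresolved dead)
  # and 121 truly alive (37 traced alive + 84 unresolved alive)
  stopifnot(length(dead_ids) >= 35, length(alive_ids) >= 121 + 71)
  set.seed(seed + 500)
  ltf_dead <- sample(dead_ids, 35)
  ltf_alive <- sample(alive_ids, 121)
  transfer_ids <- sample(setdiff(alive_ids, ltf_alive), 71)

  status <- ifelse(truth$true_dead10 == 1, "dead_documented", "alive_in_care")
  names(status) <- truth$patient_id
  status[as.character(c(ltf_dead, ltf_alive))] <- "ltf"
  status[as.character(transfer_ids)] <- "transferred"

  obs <- truth |>
    dplyr::mutate(
      status = unname(status[as.character(patient_id)]),
      last_visit_years = ifelse(status == "ltf",
                                pmin(5, death_time_years / 2, na.rm = TRUE),
                                last_visit_years),
      death_time_years = ifelse(status == "dead_documented",
                                death_time_years, NA_real_)
    ) |>
    dplyr::select(-true_dead10)
  # baseline covariate missingness at the configured rates
  set.seed(seed + 900)
  obs$weight_kg[sample(910, 27)] <- NA_real_
  cd4_miss <- sample(910, 109)
  obs$cd4[cd4_miss] <- NA_real_
  obs <- as_observed_cohort(obs)

  tracing <- tracing_result(records = tibble::tibble(
    patient_id = c(ltf_dead[1:8], ltf_alive[1:37],
                   ltf_dead[9:35], ltf_alive[38:121]),
    found = c(rep(TRUE, 45), rep(FALSE, 111)),
    dead_if_found = c(rep(1L, 8), rep(0L, 37), rep(NA_integer_, 111))
  ))
  list(obs = obs, tracing = tracing, truth = truth, cfg = cfg)
}

# Generating multivariable log-odds coefficients, in reporting-scale order.
generating_coefs <- function(cfg) {
  cf <- cfg$outcome_model
  cf[c("female", "age10", "residence_pap", "severe_poverty",
       "cd4_100", "weight10", "who_stage_advanced", "tb_baseline")]
}
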