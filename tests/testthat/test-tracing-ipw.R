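test_that("deaths among LTF are estimated from the traced fraction", {
  est <- estimate_ltf_deaths(tracing_result(n_ltf = 156, n_found = 45,
                                            n_found_dead = 8))
  expect_equal(est$death_fraction, 8 / 45)
  expect_equal(round(100 * est$death_fraction), 18)
  expect_equal(est$estimated_deaths, 28L)   # round-half-up of 156 * 8/45
  expect_equal(est$estimated_alive, 128L)

  none <- estimate_ltf_deaths(tracing_result(n_ltf = 100, n_found = 10,
                                             n_found_dead = 0))
  expect_equal(none$death_fraction, 0)
  expect_equal(none$estimated_deaths, 0L)

  all_dead <- estimate_ltf_deaths(tracing_result(n_ltf = 60, n_found = 60,
                                                 n_found_dead = 60))
  expect_equal(all_dead$death_fraction, 1)
  expect_equal(all_dead$estimated_deaths, 60L)

  expect_error(estimate_ltf_deaths(tracing_result(n_ltf = 10, n_found = 0,
                                                  n_found_dead = 0)),
               "uninformative", class = "ltfmice_tracing_error")
  expect_error(tracing_result(n_ltf = 5, n_found = 7, n_found_dead = 1),
               class = "ltfmice_tracing_error")
})

test_that("stratum completeness probabilities follow the augmented counts", {
  est <- estimate_ltf_deaths(tracing_result(156, n_found = 45, n_found_dead = 8))
  w <- stratum_ipw_weights(c(known_dead = 246, known_alive = 482, ltf = 156), est)
  alive <- w[w$stratum == "alive", ]
  expect_equal(alive$p_complete, 482 / 610)
  expect_equal(round(alive$p_complete, 2), 0.79)
  expect_equal(alive$weight, 610 / 482)

  # worked example, men only: 20 complete deaths + 60 traced deaths
  est_m <- estimate_ltf_deaths(tracing_result(60, n_found = 60, n_found_dead = 60))
  wm <- stratum_ipw_weights(c(known_dead = 20, known_alive = 20, ltf = 60), est_m)
  expect_equal(wm$p_complete[wm$stratum == "dead"], 0.25)
  expect_equal(wm$weight[wm$stratum == "dead"], 4)
  expect_equal(wm$weight[wm$stratum == "alive"], 1)

  # estimate computed for a different LTF total is refused
  expect_error(stratum_ipw_weights(c(known_dead = 10, known_alive = 10, ltf = 5),
                                   est), class = "ltfmice_ipw_error")
  # no LTF anywhere: every weight is 1
  est_none <- tibble::tibble(n_ltf = 0L, death_fraction = 0,
                             estimated_deaths = 0L, estimated_alive = 0L)
  w0 <- stratum_ipw_weights(c(known_dead = 10, known_alive = 30, ltf = 0), est_none)
  expect_equal(w0$weight, c(1, 1))

  # degenerate stratum: estimated deaths but no complete deaths
  est_d <- estimate_ltf_deaths(tracing_result(10, n_found = 5, n_found_dead = 5))
  expect_error(stratum_ipw_weights(c(known_dead = 0, known_alive = 50, ltf = 10),
                                   est_d), class = "ltfmice_ipw_error")
})

test_that("weight calibration identity and ordering invariance hold", {
  est <- estimate_ltf_deaths(tracing_result(156, n_found = 45, n_found_dead = 8))
  counts <- c(known_dead = 246, known_alive = 482, ltf = 156)
  w <- stratum_ipw_weights(counts, est)
  # weighted complete-case deaths reproduce known + estimated deaths
  expect_equal(246 * w$weight[w$stratum == "dead"], 246 + 28)
  expect_equal(482 * w$weight[w$stratum == "alive"], 482 + 128)
  # weight * p_complete = 1 in each stratum, all weights >= 1
  expect_equal(w$weight * w$p_complete, c(1, 1))
  expect_true(all(w$weight >= 1))
  # counts are aggregates: permuting patients cannot change them
  expect_identical(w, stratum_ipw_weights(counts[c(1, 2, 3)], est))
})

test_that("the published worked example reproduces end to end", {
  # complete-case view: both sexes show 50% mortality, RR = 1
  cc_table <- tibble::tibble(
    group = c("women", "women", "men", "men"),
    dead = c(1, 0, 1, 0),
    n = c(50, 50, 20, 20),
    weight = 1
  )
  cc_risk <- weighted_risk_comparison(cc_table, reference = "women")
  expect_equal(cc_risk$risk, c(0.5, 0.5))
  expect_equal(cc_risk$risk_ratio[cc_risk$group == "men"], 1)

  # after tracing: dead men weighted 4
  ipw_table <- dplyr::mutate(cc_table,
                             weight = ifelse(group == "men" & dead == 1, 4, 1))
  risk <- weighted_risk_comparison(ipw_table, reference = "women")
  expect_equal(risk$risk[risk$group == "men"], 0.8)
  expect_equal(risk$risk[risk$group == "women"], 0.5)
  expect_equal(risk$risk_ratio[risk$group == "men"], 1.6)

  # degenerate cases
  expect_equal(weighted_risk_comparison(
    tibble::tibble(group = "a", dead = 1, weight = c(2, 7)))$risk, 1)
  expect_error(weighted_risk_comparison(
    tibble::tibble(group = "a", dead = 1, weight = 0)),
    class = "ltfmice_ipw_error")
})

test_that("covariate-conditional weights nest the stratum weights", {
  cc <- small_cohort(n = 910, seed = 23)
  est <- estimate_ltf_deaths(cc$tracing)

  # covariate-free completeness model reproduces the stratum arithmetic
  wtab <- covariate_ipw_weights(cc$obs, cc$tracing, ~ 1)
  known <- cc$obs[cc$obs$status != "ltf", ]
  known_dead <- sum(known$dead10 == 1)
  known_alive <- sum(known$dead10 == 0)
  f <- cc$tracing$n_found / cc$tracing$n_attempted
  # model-based completeness in the dead stratum: documented / (documented +
  # traced-dead / f); agrees with the count-based stratum weight up to the
  # integer rounding in estimated_deaths
  p_dead_model <- known_dead / (known_dead + cc$tracing$n_found_dead / f)
  w_dead <- unique(round(wtab$weight[known$dead10 == 1], 10))
  expect_length(w_dead, 1)
  expect_equal(w_dead, 1 / p_dead_model, tolerance = 1e-8)
  strat <- stratum_ipw_weights(
    c(known_dead = known_dead, known_alive = known_alive, ltf = cc$tracing$n_ltf),
    est)
  expect_equal(w_dead, strat$weight[strat$stratum == "dead"], tolerance = 0.02)
})

test_that("worked-example covariate weights give dead men 4 and others 1", {
  obs <- worked_example_cohort()
  tr <- worked_example_tracing(obs)
  wtab <- covariate_ipw_weights(obs, tr, ~ female)
  known <- obs[obs$status != "ltf", ]
  dead_men <- known$patient_id[known$female == 0 & known$dead10 == 1]
  others <- setdiff(known$patient_id, dead_men)
  expect_equal(wtab$weight[match(dead_men, wtab$patient_id)],
               rep(4, length(dead_men)), tolerance = 1e-6)
  expect_equal(wtab$weight[match(others, wtab$patient_id)],
               rep(1, length(others)), tolerance = 1e-6)
})

test_that("partial tracing enters the completeness model as 1/f records", {
  cc <- small_cohort(n = 1200, seed = 37,
                     tracing_params = list(success_prob = 0.5))
  tr <- cc$tracing
  f <- tr$n_found / tr$n_attempted
  wtab <- covariate_ipw_weights(cc$obs, tr, ~ 1)

  # oracle: replicate each traced record 1/f times via direct weighted counts
  known <- cc$obs[cc$obs$status != "ltf", ]
  found <- tr$records[tr$records$found, ]
  for (y in 0:1) {
    n_known <- sum(known$dead10 == y)
    n_traced <- sum(found$dead_if_found == y)
    p_oracle <- n_known / (n_known + n_traced / f)
    w_model <- unique(round(wtab$weight[known$dead10 == y], 8))
    expect_equal(w_model, 1 / p_oracle, tolerance = 1e-6)
  }
})

test_that("IPW-weighted death risk is consistent under full tracing", {
  cfg <- generator_config(n_patients = 10000, seed = 77,
                          tracing_params = list(success_prob = 1))
  truth <- generate_cohort(cfg)
  obs <- apply_missingness(truth, cfg)
  tr <- simulate_tracing(obs, truth, cfg)
  res <- run_ipw(obs, tr, predictors = c("female"))
  true_risk <- mean(truth$true_dead10)
  expect_lt(abs((1 - res$survival$estimate) - true_risk), 0.02)
})

test_that("weights serialize as a two-column delimited file", {
  w <- tibble::tibble(patient_id = 1:3, weight = c(1, 1.2, 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_weights(w, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(back), c("patient_id", "weight"))
  expect_equal(back$weight, w$weight)
})
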