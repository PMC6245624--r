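test_that("spec validation enforces sensible imputation settings", {
  expect_error(imputation_spec(M = 1), class = "ltfmice_spec_error")
  expect_error(imputation_spec(k_pmm = 0), class = "ltfmice_spec_error")
  expect_error(imputation_spec(n_cycles = 0), class = "ltfmice_spec_error")
})

test_that("PMM copies donor values and respects the donor pool", {
  set.seed(1)
  # a single donor with k = 1 must be returned verbatim
  one <- pmm_impute(donor_y = 7.5,
                    donor_x = matrix(1, 1, 1),
                    missing_x = matrix(1, 3, 1), k = 1)
  expect_equal(one, rep(7.5, 3))

  # every imputed value is a member of the observed donor set
  n <- 80
  x <- cbind(1, rnorm(n))
  y <- 2 + 3 * x[, 2] + rnorm(n)
  imp <- pmm_impute(y, x, cbind(1, rnorm(40)), k = 5)
  expect_true(all(imp %in% y))
  expect_true(all(imp >= min(y) & imp <= max(y)))

  # fewer donors than k reduces the pool with a warning; zero donors error
  expect_warning(pmm_impute(y[1:3], x[1:3, , drop = FALSE],
                            cbind(1, 0), k = 5), "donor pool")
  expect_error(pmm_impute(numeric(0), matrix(0, 0, 1), cbind(1, 0)),
               class = "ltfmice_impute_error")
})

test_that("PMM imputations centre on the conditional mean (Monte-Carlo oracle)", {
  set.seed(99)
  x0 <- 0.5                       # impute at a fixed covariate value
  oracle <- 1 + 2 * x0            # conditional mean of the generating model
  n_calls <- 20
  call_means <- vapply(seq_len(n_calls), function(i) {
    # fresh donor pool per call so call means are independent draws
    xd <- rnorm(200)
    yd <- 1 + 2 * xd + rnorm(200)
    mean(pmm_impute(yd, cbind(1, xd), cbind(1, rep(x0, 100)), k = 5))
  }, numeric(1))
  se <- sd(call_means) / sqrt(n_calls)
  expect_lt(abs(mean(call_means) - oracle), 3 * se)
})

test_that("binary outcome imputation reproduces rates and associations", {
  set.seed(5)
  # predictor-free model: imputed death fraction tracks the observed 0.30
  y <- rbinom(400, 1, 0.3)
  draws <- impute_binary_outcome(y, matrix(1, 400, 1), matrix(1, 10000, 1))
  se <- sqrt(mean(y) * (1 - mean(y)) / 10000)
  # posterior-draw spread adds sampling noise beyond the binomial bound
  expect_lt(abs(mean(draws) - mean(y)), 3 * se + 3 * sd(y) / sqrt(400))

  # single-class observed outcome is an error
  expect_error(impute_binary_outcome(rep(1, 50), matrix(1, 50, 1),
                                     matrix(1, 5, 1)),
               class = "ltfmice_impute_error")

  # a strong predictor's association survives imputation
  set.seed(6)
  n <- 4000
  x <- rnorm(n)
  yy <- rbinom(n, 1, plogis(-1 + log(4) * x))
  miss <- runif(n) < 0.3
  X <- cbind(1, x)
  yy_complete <- yy
  yy_complete[miss] <- impute_binary_outcome(yy[!miss], X[!miss, ], X[miss, ])
  refit <- glm(yy_complete ~ x, family = binomial())
  ci <- suppressMessages(confint.default(refit))["x", ]
  expect_gt(log(4), ci[1])
  expect_lt(log(4), ci[2])
})

test_that("chained imputation preserves observed cells and is reproducible", {
  cc <- small_cohort(n = 500, seed = 11)
  folded <- fold_tracing(cc$obs, cc$tracing)
  spec <- imputation_spec(M = 4, n_cycles = 4, seed = 77)
  imp <- chained_imputation(folded, spec)

  expect_length(imp$datasets, 4)
  mask <- imp$missing_mask
  for (d in imp$datasets) {
    # no missing analysis values anywhere
    expect_false(anyNA(d$weight_kg))
    expect_false(anyNA(d$cd4))
    expect_false(anyNA(d$dead10))
    # observed cells bit-identical to the input
    expect_identical(d$weight_kg[!mask$weight_kg], folded$weight_kg[!mask$weight_kg])
    expect_identical(d$cd4[!mask$cd4], folded$cd4[!mask$cd4])
    expect_identical(d$dead10[!mask$dead10], folded$dead10[!mask$dead10])
    # PMM never leaves the observed range; outcome is binary
    expect_true(all(d$cd4[mask$cd4] %in% folded$cd4[!mask$cd4]))
    expect_true(all(d$weight_kg[mask$weight_kg] %in% folded$weight_kg[!mask$weight_kg]))
    expect_true(all(d$dead10[mask$dead10] %in% c(0L, 1L)))
  }

  # bit-identical reproducibility from (observed, spec, seed)
  imp2 <- chained_imputation(folded, spec)
  expect_identical(imp$datasets, imp2$datasets)
  expect_identical(imp$chain_history, imp2$chain_history)

  # streams genuinely differ: between-imputation variance is positive
  cd4_means <- vapply(imp$datasets, function(d) mean(d$cd4[mask$cd4]), numeric(1))
  expect_gt(var(cd4_means), 0)
  dead_frac <- vapply(imp$datasets, function(d) mean(d$dead10[mask$dead10]), numeric(1))
  expect_gt(var(dead_frac) + var(cd4_means), 0)

  # chain history covers every stream x iteration x variable
  expect_equal(nrow(imp$chain_history), 4 * 4 * 3)
})

test_that("zero-missing input yields M identical copies", {
  cfg <- generator_config(n_patients = 200, seed = 4,
                          ltf_model = c(intercept = -Inf), transfer_prob = 0,
                          cov_missing_rates = c(weight_kg = 0, cd4 = 0))
  obs <- apply_missingness(generate_cohort(cfg), cfg)
  imp <- chained_imputation(obs, imputation_spec(M = 3, n_cycles = 2, seed = 1))
  expect_identical(imp$datasets[[1]]$cd4, obs$cd4)
  expect_equal(imp$datasets[[1]], imp$datasets[[2]], ignore_attr = TRUE)
  expect_equal(nrow(imp$chain_history), 0)
})

test_that("excessive missingness is refused, heavy missingness warned about", {
  cc <- small_cohort(n = 300, seed = 15,
                     cov_missing_rates = c(weight_kg = 0.03, cd4 = 0.55))
  expect_error(chained_imputation(fold_tracing(cc$obs, cc$tracing),
                                  imputation_spec(M = 2, n_cycles = 1, seed = 1)),
               class = "ltfmice_impute_error")
  cc2 <- small_cohort(n = 600, seed = 16,
                      cov_missing_rates = c(weight_kg = 0.03, cd4 = 0.40))
  expect_warning(chained_imputation(fold_tracing(cc2$obs, cc2$tracing),
                                    imputation_spec(M = 2, n_cycles = 1, seed = 1)),
                 "30%")
})

test_that("diagnostics summarise imputed vs observed and chain stationarity", {
  cc <- small_cohort(n = 910, seed = 19)
  folded <- fold_tracing(cc$obs, cc$tracing)
  imp <- chained_imputation(folded, imputation_spec(M = 5, n_cycles = 6, seed = 3))
  diag <- imputation_diagnostics(imp, folded)

  vs <- diag$value_summary
  expect_setequal(vs$variable, c("weight_kg", "cd4"))
  # imputed CD4 median falls inside the observed IQR (distributional sanity)
  cd4_row <- vs[vs$variable == "cd4", ]
  expect_gt(cd4_row$imputed_median, cd4_row$observed_q1)
  expect_lt(cd4_row$imputed_median, cd4_row$observed_q3)

  expect_equal(diag$outcome_summary$n_imputed_outcomes,
               sum(folded$status == "ltf"))
  expect_true(diag$outcome_summary$imputed_death_proportion >= 0 &&
                diag$outcome_summary$imputed_death_proportion <= 1)

  # stationary chains: no significant trend for the continuous variables
  trend <- diag$chain_trend
  expect_setequal(trend$variable, c("weight_kg", "cd4", "dead10"))
  expect_true(all(trend$p_value[trend$variable != "dead10"] > 0.01))

  # zero-missing cohort produces empty summaries
  cfg0 <- generator_config(n_patients = 150, seed = 8,
                           ltf_model = c(intercept = -Inf), transfer_prob = 0,
                           cov_missing_rates = c(weight_kg = 0, cd4 = 0))
  obs0 <- apply_missingness(generate_cohort(cfg0), cfg0)
  imp0 <- chained_imputation(obs0, imputation_spec(M = 2, n_cycles = 2, seed = 1))
  d0 <- imputation_diagnostics(imp0, obs0)
  expect_equal(nrow(d0$value_summary), 0)
  expect_equal(nrow(d0$outcome_summary), 0)
})

test_that("MNAR loss biases MICE increasingly with the outcome dependence", {
  bias_at <- function(mnar_beta) {
    biases <- vapply(1:2, function(r) {
      cfg <- generator_config(
        n_patients = 1500, seed = 600 + 10 * r,
        ltf_model = c(intercept = -0.653 - mnar_beta * 0.3,
                      true_dead10 = mnar_beta))
      truth <- generate_cohort(cfg)
      obs <- apply_missingness(truth, cfg)
      imp <- chained_imputation(obs, imputation_spec(M = 4, n_cycles = 4,
                                                     seed = 1000 + r))
      pooled_dead <- mean(vapply(imp$datasets, function(d) mean(d$dead10),
                                 numeric(1)))
      abs(pooled_dead - mean(truth$true_dead10))
    }, numeric(1))
    mean(biases)
  }
  b0 <- bias_at(0)
  b1 <- bias_at(1.5)
  b2 <- bias_at(3)
  expect_lt(b0, b2)
  expect_lt(b1, b2 + 0.01)
  expect_lt(b0, b1 + 0.01)
})

test_that("imputation sets serialize with a manifest", {
  cc <- small_cohort(n = 200, seed = 25)
  folded <- fold_tracing(cc$obs, cc$tracing)
  imp <- chained_imputation(folded, imputation_spec(M = 3, n_cycles = 2, seed = 5))
  dir <- withr::local_tempdir()
  write_imputations(imp, dir)
  files <- list.files(dir)
  expect_true(all(sprintf("imputation_%02d.csv", 1:3) %in% files))
  expect_true("manifest.json" %in% files)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$M, 3)
  expect_length(manifest$stream_seeds, 3)
  back <- readr::read_csv(file.path(dir, "imputation_02.csv"),
                          show_col_types = FALSE)
  expect_equal(back$cd4, imp$datasets[[2]]$cd4)
})
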