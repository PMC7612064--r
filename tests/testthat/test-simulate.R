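test_that("simulation is byte-identical under a fixed seed", {
  cf <- sim_config(n_participants = 25, seed = 77)
  s1 <- simulate_cohort(cf)
  s2 <- simulate_cohort(cf)
  expect_identical(s1, s2)
  s3 <- simulate_cohort(sim_config(n_participants = 25, seed = 78))
  expect_false(identical(s1$cohort, s3$cohort))
})

test_that("a seed is mandatory and invalid covariances are refused", {
  expect_error(sim_config(n_participants = 10), class = "lagmed_input_error")
  expect_error(sim_config(n_participants = 10, seed = 1,
                          var_a = 1e-5, var_c = 1e-4, cov_ac = 1e-3),
               class = "lagmed_input_error")
})

test_that("design margins match the intended study conditions", {
  sim <- simulate_cohort(sim_config(n_participants = 300, seed = 42))
  tr <- sim$truth$participants
  expect_gt(mean(tr$n_sessions), 11.3)
  expect_lt(mean(tr$n_sessions), 13.3)
  expect_true(all(tr$n_sessions >= 5 & tr$n_sessions <= 26))
  dur <- sim$cohort |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(d = max(days_since_first_session))
  expect_gt(mean(dur$d), 170)
  expect_lt(mean(dur$d), 240)
  # realized slope heterogeneity approaches the configured variance
  sim_big <- simulate_cohort(sim_config(n_participants = 1000, seed = 4,
                                        missing_prob = 0))
  expect_equal(var(sim_big$truth$participants$a_i), 3.6e-5, tolerance = 0.1)
})

test_that("without missingness or clipping every participant yields sessions-1 lagged rows", {
  cf <- sim_config(n_participants = 20, seed = 9, missing_prob = 0,
                   bounds_m = c(-100, 100), bounds_y = c(-500, 500),
                   extra_process_vars = list())
  sim <- simulate_cohort(cf)
  expect_true(all(sim$clipping$n_clipped == 0))
  lag <- build_lagged_dataset(sim$cohort, "sfa", "social_anxiety")
  counts <- lag |> dplyr::count(participant_id)
  expect_equal(counts$n, sim$truth$participants$n_sessions - 1)
})

test_that("deterministic limit lies exactly on the generating lines", {
  cf <- sim_config(n_participants = 5, seed = 2, var_a = 0, var_c = 0,
                   cov_ac = 0, var_intercept_m = 0, var_intercept_y = 0,
                   sigma_m = 1e-9, sigma_y = 1e-9, missing_prob = 0,
                   bounds_m = c(-100, 100), bounds_y = c(-500, 500),
                   extra_process_vars = list())
  sim <- simulate_cohort(cf)
  t <- sim$cohort$days_since_first_session
  expect_equal(sim$cohort$sfa, cf$intercept_m + cf$a * t, tolerance = 1e-6)
})

test_that("configurations implying heavy clipping are refused with guidance", {
  cf <- sim_config(n_participants = 10, seed = 3, intercept_m = -6)
  expect_error(simulate_cohort(cf), class = "lagmed_input_error",
               regexp = "clipping")
})

test_that("item-level simulation round-trips through SPWSS scoring", {
  items <- simulate_spwss_items(c(21, 0, 32, 13.4), c(5.5, 0, 8, 3.2))
  scored <- items |>
    dplyr::group_by(occasion) |>
    dplyr::group_modify(~ score_spwss(.x)) |>
    dplyr::ungroup()
  expect_equal(scored$social_anxiety, c(21, 0, 32, 13))
  expect_equal(scored$sfa, c(5.5, 0, 8, 3))
  expect_true(all(items$value >= 0 & items$value <= 8))
})

test_that("indirect-effect direction is recovered and exceeds the reversed model", {
  forward_ab <- numeric(3)
  reversed_pm <- forward_pm <- numeric(3)
  for (r in 1:3) {
    cf <- sim_config(n_participants = 80, seed = 400 + r,
                     extra_process_vars = list())
    sim <- simulate_cohort(cf)
    fwd <- sim$cohort |>
      build_lagged_dataset("sfa", "social_anxiety") |>
      center_within_between() |>
      fit_mediation(mediation_spec("sfa", "social_anxiety"),
                    fit_control(variance_hessian = FALSE))
    rev <- sim$cohort |>
      build_lagged_dataset("social_anxiety", "sfa") |>
      center_within_between() |>
      fit_mediation(reverse_model(mediation_spec("social_anxiety", "sfa")),
                    fit_control(variance_hessian = FALSE))
    forward_ab[r] <- indirect_effect(fwd)$ab
    forward_pm[r] <- indirect_effect(fwd)$pm
    reversed_pm[r] <- indirect_effect(rev)$pm
  }
  expect_true(all(forward_ab < 0))
  expect_gte(sum(forward_pm > reversed_pm), 2)
})

test_that("parameter recovery summarises bias, coverage, and convergence", {
  cf <- sim_config(n_participants = 40, seed = 55,
                   extra_process_vars = list())
  rec <- parameter_recovery(cf, n_reps = 3)
  expect_setequal(rec$parameter, c("a", "b", "c_prime", "var_a", "var_c"))
  expect_true(all(rec$convergence_rate >= 0 & rec$convergence_rate <= 1))
  reps <- attr(rec, "replicates")
  expect_equal(nrow(reps), 3)
  expect_true(all(c("p_b", "se_a") %in% names(reps)))
  # null b: mean estimate within 2 Monte Carlo SEs of zero
  cf0 <- sim_config(n_participants = 60, seed = 56, b = 0,
                    extra_process_vars = list())
  rec0 <- parameter_recovery(cf0, n_reps = 4)
  reps0 <- attr(rec0, "replicates")
  mc_se <- sd(reps0$b) / sqrt(nrow(reps0))
  expect_lt(abs(mean(reps0$b)), 2 * mc_se + 1e-8)
})

test_that("doubling the sample size shrinks RMSE(a) at the root-n rate", {
  cf1 <- sim_config(n_participants = 50, seed = 500,
                    extra_process_vars = list())
  cf2 <- sim_config(n_participants = 100, seed = 500,
                    extra_process_vars = list())
  r1 <- parameter_recovery(cf1, n_reps = 50)
  r2 <- parameter_recovery(cf2, n_reps = 50)
  ratio <- r2$rmse[r2$parameter == "a"] / r1$rmse[r1$parameter == "a"]
  expect_gt(ratio, 1 / sqrt(2) * 0.7)
  expect_lt(ratio, 1 / sqrt(2) * 1.3)
})
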