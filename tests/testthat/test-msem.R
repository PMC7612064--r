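default_spec <- mediation_spec("sfa", "social_anxiety")

small_centered <- function(seed = 1, n = 30) {
  sim <- simulate_cohort(sim_config(n_participants = n, seed = seed))
  sim$cohort |>
    build_lagged_dataset("sfa", "social_anxiety") |>
    center_within_between()
}

test_that("likelihood reduces to independent univariate densities without random effects", {
  cen <- random_centered_instance(11, n_participants = 1, max_rows = 3)
  pn <- msem_parameter_names(cen, default_spec)
  beta <- c(intercept_m = 5, a = -0.01, t_between_m = 0.02,
            intercept_y = 20, b = 0.5, c_prime = -0.03,
            t_between_y = -0.01, m_between_y = 0.1)
  s2m <- 0.8; s2y <- 4
  theta <- setNames(c(rep(-40, 4), 0, log(s2m), log(s2y)), pn[-(1:8)])
  nll <- negative_log_likelihood(c(beta, theta), cen, default_spec)
  mu_m <- beta["intercept_m"] + beta["a"] * cen$tprev_within +
    beta["t_between_m"] * cen$tprev_between
  mu_y <- beta["intercept_y"] + beta["b"] * cen$m_within +
    beta["c_prime"] * cen$t_within + beta["t_between_y"] * cen$t_between +
    beta["m_between_y"] * cen$m_between
  by_hand <- -sum(stats::dnorm(cen$m_prev, mu_m, sqrt(s2m), log = TRUE)) -
    sum(stats::dnorm(cen$y_j, mu_y, sqrt(s2y), log = TRUE))
  expect_equal(nll, by_hand, tolerance = 1e-6)
})

test_that("duplicating a participant doubles the negative log-likelihood", {
  cen <- random_centered_instance(4, n_participants = 1, max_rows = 4)
  dup <- dplyr::bind_rows(cen, dplyr::mutate(cen, participant_id = 2))
  params <- withr::with_seed(8, c(rnorm(8), rnorm(7, sd = 0.5)))
  expect_equal(
    negative_log_likelihood(params, dup, default_spec),
    2 * negative_log_likelihood(params, cen, default_spec),
    tolerance = 1e-10)
})

test_that("likelihood matches the dense multivariate-normal oracle", {
  specs <- list(
    default_spec,
    mediation_spec("sfa", "social_anxiety",
                   estimate_random_correlation = FALSE),
    mediation_spec("sfa", "social_anxiety", b_random = TRUE),
    mediation_spec("sfa", "social_anxiety",
                   estimate_cross_equation_residual_covariance = TRUE))
  for (s in 1:4) {
    cen <- random_centered_instance(100 + s, n_participants = 4, max_rows = 4)
    for (spec in specs) {
      n_par <- length(msem_parameter_names(cen, spec))
      params <- withr::with_seed(200 + s, c(rnorm(8), rnorm(n_par - 8, sd = 0.6)))
      expect_equal(
        negative_log_likelihood(params, cen, spec),
        dense_nll_oracle(params, cen, spec),
        tolerance = 1e-8)
    }
  }
})

test_that("noise-free data with degenerate random effects is recovered exactly", {
  df <- noise_free_cohort(a = -0.01, b = 0.8, c_prime = -0.03)
  cen <- df |>
    build_lagged_dataset("m", "y") |>
    center_within_between()
  fit <- fit_mediation(cen, mediation_spec("m", "y"),
                       fit_control(variance_hessian = FALSE))
  expect_equal(unname(fit$beta["a"]), -0.01, tolerance = 1e-6)
  expect_equal(unname(fit$beta["b"]), 0.8, tolerance = 1e-6)
  expect_equal(unname(fit$beta["c_prime"]), -0.03, tolerance = 1e-6)
})

test_that("estimates are invariant to participant and row ordering", {
  cen <- small_centered(21)
  fit1 <- fit_mediation(cen, default_spec, fit_control(variance_hessian = FALSE))
  shuffled <- withr::with_seed(5, cen[sample(nrow(cen)), ])
  fit2 <- fit_mediation(shuffled, default_spec,
                        fit_control(variance_hessian = FALSE))
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-4)
  expect_equal(fit1$theta, fit2$theta, tolerance = 1e-4)
})

test_that("M-equation estimates agree with an independent mixed-model fitter", {
  cen <- small_centered(31, n = 60)
  spec <- mediation_spec("sfa", "social_anxiety",
                         estimate_random_correlation = FALSE)
  fit <- fit_mediation(cen, spec, fit_control(variance_hessian = FALSE))
  # raw-days covariates trip lme4's scaling heuristics; harmless here
  lmer_fit <- suppressWarnings(lme4::lmer(
    m_prev ~ tprev_within + tprev_between +
      (1 + tprev_within || participant_id),
    data = cen, REML = FALSE,
    control = lme4::lmerControl(optimizer = "bobyqa")))
  expect_equal(unname(fit$beta["a"]),
               unname(lme4::fixef(lmer_fit)["tprev_within"]),
               tolerance = 1e-3)
  vc <- as.data.frame(lme4::VarCorr(lmer_fit))
  var_a_lmer <- vc$vcov[vc$var1 == "tprev_within" & !is.na(vc$var1)]
  expect_equal(unname(fit$random_variances["var_a_dev"]), var_a_lmer,
               tolerance = 1e-3)
})

test_that("random-intercept reduction reproduces the ICC estimate", {
  sim <- simulate_cohort(sim_config(n_participants = 40, seed = 13))
  icc_lme4 <- compute_icc(sim$cohort, "sfa")
  icc_own <- fit_random_intercept(sim$cohort, "sfa")$icc
  expect_equal(icc_own, icc_lme4, tolerance = 1e-6)
})

test_that("indirect effect arithmetic is internally consistent", {
  cen <- small_centered(7)
  fit <- fit_mediation(cen, default_spec)
  ie <- indirect_effect(fit)
  expect_equal(ie$ab, unname(fit$beta["a"] * fit$beta["b"]) + ie$sigma_ab)
  expect_identical(ie$sigma_ab, 0)  # fixed b
  V <- vcov(fit)
  se_manual <- sqrt(fit$beta["b"]^2 * V["a", "a"] +
                      fit$beta["a"]^2 * V["b", "b"] +
                      2 * fit$beta["a"] * fit$beta["b"] * V["a", "b"])
  expect_equal(ie$se_ab, unname(se_manual))
  expect_equal(round(ie$pm),
               round(100 * ie$ab / (ie$ab + ie$c_prime)))
  # Monte Carlo interval is reproducible and brackets the delta interval
  mc1 <- indirect_effect(fit, ci_method = "montecarlo", seed = 99)
  mc2 <- indirect_effect(fit, ci_method = "montecarlo", seed = 99)
  expect_identical(mc1, mc2)
  expect_lt(mc1$ci_lower, ie$ab)
  expect_gt(mc1$ci_upper, ie$ab)
})

test_that("percent mediation follows the simplified formula and flags edge cases", {
  expect_equal(round(as.numeric(percent_mediation(-0.011 * 1.922, -0.029))), 42)
  expect_equal(as.numeric(percent_mediation(0, -0.04)), 0)
  expect_equal(round(as.numeric(percent_mediation(-0.053 * 0.096, -0.006))), 46)
  z <- percent_mediation(0.05, -0.05)
  expect_true(is.nan(as.numeric(z)))
  expect_identical(attr(z, "flag"), "zero_denominator")
  o <- percent_mediation(0.05, -0.02)
  expect_identical(attr(o, "flag"), "out_of_range")
  expect_gt(as.numeric(o), 100)
  # complement identity: mediated plus direct share is exactly 100
  for (ab in c(-0.02, 0.01, 0.3)) {
    for (cp in c(-0.03, 0.05)) {
      pm <- as.numeric(percent_mediation(ab, cp))
      expect_equal(pm + 100 * cp / (ab + cp), 100)
    }
  }
})

test_that("reverse_model swaps roles and is an involution", {
  spec <- mediation_spec("sfa", "social_anxiety", se_method = "sandwich")
  rev <- reverse_model(spec)
  expect_identical(rev$process_var, "social_anxiety")
  expect_identical(rev$outcome_var, "sfa")
  expect_true(rev$reversed)
  expect_identical(rev$se_method, "sandwich")
  expect_identical(reverse_model(rev), spec)
})

test_that("Wald tests report normal-theory statistics on the right scales", {
  cen <- small_centered(17)
  fit <- fit_mediation(cen, default_spec)
  wt <- wald_tests(fit)
  expect_setequal(unique(wt$scale), c("natural", "unconstrained"))
  expect_equal(wt$statistic, wt$estimate / wt$se)
  expect_equal(wt$p.value, 2 * pnorm(-abs(wt$statistic)))
  expect_equal(wt$conf.high - wt$conf.low, 2 * qnorm(0.975) * wt$se)
  expect_false(any(wt$flagged))
  # broom-style accessors agree
  expect_equal(tidy(fit, effects = "fixed")$estimate, unname(fit$beta))
  g <- glance(fit)
  expect_equal(g$logLik, fit$logLik)
  expect_true(g$converged)
})

test_that("sandwich standard errors differ from model-based but keep estimates", {
  cen <- small_centered(23)
  fit_mb <- fit_mediation(cen, default_spec, fit_control(variance_hessian = FALSE))
  fit_sw <- fit_mediation(cen, mediation_spec("sfa", "social_anxiety",
                                              se_method = "sandwich"),
                          fit_control(variance_hessian = FALSE))
  expect_equal(fit_mb$beta, fit_sw$beta, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(diag(fit_mb$vcov_beta),
                                diag(fit_sw$vcov_beta))))
})

test_that("fitting refuses unsupported inputs with labelled errors", {
  cen <- small_centered(3)
  expect_error(fit_mediation(cen[cen$participant_id == 1, ], default_spec),
               class = "lagmed_input_error")
  expect_error(fit_mediation(dplyr::select(cen, -m_within), default_spec),
               class = "lagmed_input_error")
})
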