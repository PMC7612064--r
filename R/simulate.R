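# Synthetic session-by-session cohort generator.
#
# Emulates routine-practice weekly therapy monitoring: roughly weekly
# sessions drifting towards wider spacing, a few monthly booster sessions at
# the end of treatment, within-person improvement over time with
# heterogeneous slopes, lag-1 coupling from the (within-person-centered)
# process variable to the outcome, and occasional missed questionnaires.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the pre-2008 clinic sample the pipeline was designed
#' around: 185 participants, sessions drawn from a rounded normal with mean
#' 12.3 and SD 2.9 (truncated to 5-26), session spacing that averages about
#' 204 days of treatment (routine-practice weekly sessions that slip towards
#' ten-day gaps, plus up to three monthly-or-wider booster gaps at the end),
#' true paths set to the self-focused-attention model estimates (a = -0.013
#' per day on a 0-8 process scale, b = 0.821, c' = -0.039 per day on a 0-32
#' outcome scale), and variance components calibrated so the intraclass
#' correlations of both variables fall in the .43-.68 screening band.
#'
#' @param n_participants Number of participants (default 185).
#' @param sessions_mean,sessions_sd,sessions_min,sessions_max Session-count
#'   distribution (rounded normal, truncated).
#' @param weekly_gap_mean,weekly_gap_sd Spacing (days) of regular sessions,
#'   truncated to \[3, 28\].
#' @param n_booster,booster_gap_mean,booster_gap_sd Number of end-of-
#'   treatment booster gaps and their spacing (days), truncated to \[21, 90\].
#' @param process_name,outcome_name Column names for the primary process
#'   variable and the outcome.
#' @param a,b,c_prime True paths: process-on-time slope (per day), lagged
#'   within-process-on-outcome slope, direct time-on-outcome slope (per day).
#' @param var_a,var_c Random-slope variances; `cov_ac` their covariance.
#' @param intercept_m,var_intercept_m,sigma_m Process-variable intercept
#'   mean, between-person intercept variance, residual SD.
#' @param intercept_y,var_intercept_y,sigma_y Outcome counterparts.
#' @param bounds_m,bounds_y Scale bounds for clipping (length-2 numeric or
#'   `NULL` for an unbounded composite).
#' @param missing_prob Probability that an occasion after the first has all
#'   questionnaires missing (session attended, questionnaire skipped).
#' @param extra_process_vars Optional named list of secondary process
#'   variables, each a list with `a`, `sd_a`, `intercept`, `sd_intercept`,
#'   `resid_sd`, `bounds`; they trend over time but are not coupled to the
#'   outcome.
#' @param centered_coupling Couple the outcome to the within-person-centered
#'   lagged process (default `TRUE`, matching the estimator); `FALSE`
#'   couples to the uncentered value for misspecification experiments.
#' @param seed Mandatory integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 185,
                       sessions_mean = 12.3, sessions_sd = 2.9,
                       sessions_min = 5, sessions_max = 26,
                       weekly_gap_mean = 10, weekly_gap_sd = 4,
                       n_booster = 3, booster_gap_mean = 40,
                       booster_gap_sd = 12,
                       process_name = "sfa", outcome_name = "social_anxiety",
                       a = -0.013, b = 0.821, c_prime = -0.039,
                       var_a = 3.6e-5, var_c = 7.5e-4,
                       cov_ac = 0.3 * sqrt(3.6e-5 * 7.5e-4),
                       intercept_m = 5.3, var_intercept_m = 1.4,
                       sigma_m = 0.9,
                       intercept_y = 21, var_intercept_y = 16,
                       sigma_y = 2.5,
                       bounds_m = c(0, 8), bounds_y = c(0, 32),
                       missing_prob = 0.12,
                       extra_process_vars = default_extra_process_vars(),
                       centered_coupling = TRUE,
                       seed) {
  if (missing(seed) || is.null(seed)) {
    abort("sim_config: a seed is mandatory", class = "lagmed_input_error")
  }
  stopifnot(var_a >= 0, var_c >= 0, var_intercept_m >= 0,
            var_intercept_y >= 0, sigma_m > 0, sigma_y > 0,
            missing_prob >= 0, missing_prob < 1)
  if (var_a > 0 && var_c > 0 && abs(cov_ac) > sqrt(var_a * var_c)) {
    abort("sim_config: cov_ac violates positive semi-definiteness",
          class = "lagmed_input_error")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_extra_process_vars <- function() {
  list(
    scq_composite = list(a = -0.011, sd_a = 0.005, intercept = 1.38,
                         sd_intercept = 0.95, resid_sd = 0.7, bounds = NULL),
    depressed_mood = list(a = -0.045, sd_a = 0.02, intercept = 18.3,
                          sd_intercept = 9, resid_sd = 4.5, bounds = c(0, 63)))
}

clip_to_bounds <- function(x, bounds) {
  if (is.null(bounds)) return(list(x = x, n_clipped = 0L))
  clipped <- sum(!is.na(x) & (x < bounds[1] | x > bounds[2]))
  list(x = pmin(pmax(x, bounds[1]), bounds[2]), n_clipped = clipped)
}

#' Simulate a session-by-session therapy cohort
#'
#' Draws per-participant random intercepts and slopes, generates occasion
#' days (weekly-ish spacing with end-of-treatment boosters), builds the
#' process variable as `intercept + a_i * t + noise` and the outcome as
#' `intercept + b * (lagged process, within-person centered) + c'_i * t +
#' noise`, clips to scale bounds, and applies occasion-level missingness.
#' Byte-identical under a fixed seed.
#'
#' @param config A [sim_config] object.
#' @return A list with `cohort` (long scored tibble: `participant_id`,
#'   `session_index`, `days_since_first_session`, outcome and process
#'   columns), `truth` (per-participant realized slopes/intercepts and the
#'   population parameters), and `clipping` (per-variable clipping rates).
#'   Configurations implying more than 50% clipping on any variable are
#'   refused.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  withr::with_seed(cf$seed, {
    n <- cf$n_participants
    n_sessions <- pmin(pmax(round(rnorm(n, cf$sessions_mean, cf$sessions_sd)),
                            cf$sessions_min), cf$sessions_max)

    # correlated (a_i, c_i) random slopes
    Sig <- matrix(c(cf$var_a, cf$cov_ac, cf$cov_ac, cf$var_c), 2, 2)
    ev <- eigen(Sig, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors)
    slopes <- matrix(rnorm(2 * n), n, 2) %*% L
    a_i <- cf$a + slopes[, 1]
    c_i <- cf$c_prime + slopes[, 2]
    int_m_i <- rnorm(n, cf$intercept_m, sqrt(cf$var_intercept_m))
    int_y_i <- rnorm(n, cf$intercept_y, sqrt(cf$var_intercept_y))

    extra_re <- purrr::imap(cf$extra_process_vars, function(vv, nm) {
      list(a = rnorm(n, vv$a, vv$sd_a),
           int = rnorm(n, vv$intercept, vv$sd_intercept))
    })

    clip_counts <- c(setNames(0L, cf$process_name),
                     setNames(0L, cf$outcome_name),
                     setNames(rep(0L, length(cf$extra_process_vars)),
                              names(cf$extra_process_vars)))
    totals <- clip_counts

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      ns <- n_sessions[i]
      n_boost <- min(cf$n_booster, ns - 1)
      n_weekly <- ns - 1 - n_boost
      gaps <- c(
        pmin(pmax(rnorm(n_weekly, cf$weekly_gap_mean, cf$weekly_gap_sd), 3), 28),
        pmin(pmax(rnorm(n_boost, cf$booster_gap_mean, cf$booster_gap_sd), 21), 90))
      t <- c(0, cumsum(round(gaps)))

      m_raw <- int_m_i[i] + a_i[i] * t + rnorm(ns, 0, cf$sigma_m)
      cm <- clip_to_bounds(m_raw, cf$bounds_m)
      m <- cm$x
      clip_counts[cf$process_name] <- clip_counts[cf$process_name] + cm$n_clipped
      totals[cf$process_name] <- totals[cf$process_name] + ns

      m_center <- if (cf$centered_coupling) mean(m) else 0
      y <- int_y_i[i] + c_i[i] * t + rnorm(ns, 0, cf$sigma_y)
      if (ns >= 2) {
        y[2:ns] <- y[2:ns] + cf$b * (m[1:(ns - 1)] - m_center)
      }
      cy <- clip_to_bounds(y, cf$bounds_y)
      y <- cy$x
      clip_counts[cf$outcome_name] <- clip_counts[cf$outcome_name] + cy$n_clipped
      totals[cf$outcome_name] <- totals[cf$outcome_name] + ns

      df <- tibble::tibble(
        participant_id = i,
        session_index = seq_len(ns),
        days_since_first_session = t)
      df[[cf$outcome_name]] <- y
      df[[cf$process_name]] <- m
      for (nm in names(cf$extra_process_vars)) {
        vv <- cf$extra_process_vars[[nm]]
        v_raw <- extra_re[[nm]]$int[i] + extra_re[[nm]]$a[i] * t +
          rnorm(ns, 0, vv$resid_sd)
        cv <- clip_to_bounds(v_raw, vv$bounds)
        df[[nm]] <- cv$x
        clip_counts[nm] <- clip_counts[nm] + cv$n_clipped
        totals[nm] <- totals[nm] + ns
      }

      # missed questionnaires: session attended, all scores missing
      if (cf$missing_prob > 0 && ns >= 2) {
        miss <- c(FALSE, stats::runif(ns - 1) < cf$missing_prob)
        score_cols <- setdiff(names(df), c("participant_id", "session_index",
                                           "days_since_first_session"))
        df[miss, score_cols] <- NA_real_
      }
      rows[[i]] <- df
    }

    clipping <- tibble::tibble(
      variable = names(clip_counts),
      n_clipped = as.integer(clip_counts),
      n_values = as.integer(totals),
      rate = as.numeric(clip_counts) / pmax(as.numeric(totals), 1))
    if (any(clipping$rate > 0.5)) {
      abort(paste0("simulate_cohort: configuration implies >50% clipping on ",
                   paste(clipping$variable[clipping$rate > 0.5], collapse = ", "),
                   "; widen the bounds or shrink intercept/slope magnitudes"),
            class = "lagmed_input_error")
    }

    list(
      cohort = dplyr::bind_rows(rows),
      truth = list(
        participants = tibble::tibble(
          participant_id = seq_len(n), a_i = a_i, c_i = c_i,
          intercept_m = int_m_i, intercept_y = int_y_i,
          n_sessions = n_sessions),
        population = list(a = cf$a, b = cf$b, c_prime = cf$c_prime,
                          var_a = cf$var_a, var_c = cf$var_c,
                          cov_ac = cf$cov_ac,
                          sigma2_m = cf$sigma_m^2, sigma2_y = cf$sigma_y^2)),
      clipping = clipping)
  })
}

#' Draw SPWSS item responses consistent with target scale scores
#'
#' Item-level companion of the generator, used to exercise the scoring
#' module: distributes a 4-item social anxiety total and a 2-item
#' self-focused attention mean over integer 0-8 item responses.
#'
#' @param social_anxiety_total Vector of targets in \[0, 32\].
#' @param sfa_mean Vector of targets in \[0, 8\].
#' @return Long tibble with `occasion`, `item`, `value`; rescoring with
#'   [score_spwss()] recovers the rounded targets.
#' @export
simulate_spwss_items <- function(social_anxiety_total, sfa_mean) {
  stopifnot(length(social_anxiety_total) == length(sfa_mean))
  spread_total <- function(total, k, cap) {
    total <- max(0, min(round(total), k * cap))
    base <- rep(total %/% k, k)
    rem <- total - sum(base)
    if (rem > 0) base[seq_len(rem)] <- base[seq_len(rem)] + 1
    while (any(base > cap)) {  # redistribute overflow
      over <- which.max(base); under <- which.min(base)
      base[over] <- base[over] - 1; base[under] <- base[under] + 1
    }
    base
  }
  purrr::map2_dfr(social_anxiety_total, sfa_mean, function(tot, sf) {
    anx <- spread_total(tot, 4, 8)
    sfa2 <- spread_total(round(sf * 2), 2, 8)
    tibble::tibble(item = c(spwss_items$anxiety, spwss_items$sfa),
                   value = c(anx, sfa2))
  }, .id = "occasion") |>
    dplyr::mutate(occasion = as.integer(.data$occasion))
}

#' Parameter-recovery study
#'
#' Repeatedly simulates a cohort, builds the lagged centered dataset for the
#' primary process variable, fits the mediation model, and summarises bias,
#' RMSE, confidence-interval coverage, and convergence across replicates.
#' Each replicate uses a seed derived deterministically from the config seed.
#'
#' @param config A [sim_config]; its `a`, `b`, `c_prime`, `var_a`, `var_c`
#'   are the recovery truth.
#' @param n_reps Number of replicates (>= 2).
#' @param level CI level used for coverage (default 0.95).
#' @param control A [fit_control]; variance-parameter Hessians are off by
#'   default here since coverage is assessed for the fixed effects.
#' @return Tibble with one row per parameter (`a`, `b`, `c_prime`, `var_a`,
#'   `var_c`): truth, mean estimate, bias, RMSE, CI coverage (fixed effects
#'   only), convergence rate. The replicate-level estimates are attached as
#'   attribute `"replicates"` (including each replicate's p-value for b, for
#'   null-calibration studies).
#' @export
parameter_recovery <- function(config, n_reps, level = 0.95,
                               control = fit_control(variance_hessian = FALSE)) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 2)
  zc <- qnorm(1 - (1 - level) / 2)
  spec <- mediation_spec(config$process_name, config$outcome_name)

  reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
    cf <- config
    cf$seed <- (config$seed + r * 10007L) %% 2147483647L
    sim <- simulate_cohort(cf)
    centered <- sim$cohort |>
      build_lagged_dataset(config$process_name, config$outcome_name) |>
      center_within_between()
    fit <- tryCatch(fit_mediation(centered, spec, control),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(rep = r, converged = FALSE))
    }
    se <- sqrt(pmax(diag(fit$vcov_beta), 0))
    tibble::tibble(
      rep = r, converged = fit$converged,
      a = unname(fit$beta["a"]), se_a = unname(se["a"]),
      b = unname(fit$beta["b"]), se_b = unname(se["b"]),
      c_prime = unname(fit$beta["c_prime"]), se_c = unname(se["c_prime"]),
      var_a = unname(fit$random_variances["var_a_dev"]),
      var_c = unname(fit$random_variances["var_c_dev"]),
      p_b = 2 * pnorm(-abs(fit$beta["b"] / se["b"])))
  })

  ok <- reps[!is.na(reps$a), ]
  truth <- c(a = config$a, b = config$b, c_prime = config$c_prime,
             var_a = config$var_a, var_c = config$var_c)
  cover <- function(est, se, tr) {
    mean(tr >= est - zc * se & tr <= est + zc * se, na.rm = TRUE)
  }
  mean_est <- c(mean(ok$a), mean(ok$b), mean(ok$c_prime),
                mean(ok$var_a, na.rm = TRUE), mean(ok$var_c, na.rm = TRUE))
  rmse <- c(sqrt(mean((ok$a - truth["a"])^2)),
            sqrt(mean((ok$b - truth["b"])^2)),
            sqrt(mean((ok$c_prime - truth["c_prime"])^2)),
            sqrt(mean((ok$var_a - truth["var_a"])^2, na.rm = TRUE)),
            sqrt(mean((ok$var_c - truth["var_c"])^2, na.rm = TRUE)))
  coverage <- c(cover(ok$a, ok$se_a, truth["a"]),
                cover(ok$b, ok$se_b, truth["b"]),
                cover(ok$c_prime, ok$se_c, truth["c_prime"]),
                NA_real_, NA_real_)
  summary <- tibble::tibble(
    parameter = names(truth),
    truth = as.numeric(truth),
    mean_estimate = mean_est,
    bias = mean_est - as.numeric(truth),
    rmse = rmse,
    ci_coverage = coverage,
    convergence_rate = mean(reps$converged))
  attr(summary, "replicates") <- reps
  summary
}
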