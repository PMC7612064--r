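# Maximum-likelihood machinery for the two-equation lagged mediation model.
#
# Per participant the stacked response vector is (process rows, outcome rows):
#   M equation:  m_prev ~ intercept_m + a * tprev_within + t_between_m * tprev_between
#                + random intercept + random a deviation
#   Y equation:  y_j ~ intercept_y + b * m_within + c' * t_within
#                + t_between_y * t_between + m_between_y * m_between
#                + random intercept + random c' deviation
# Random effects are jointly Gaussian; residuals are diagonal per equation
# (optionally with a cross-equation covariance between a row's two
# responses). Fixed effects are profiled out by GLS inside the likelihood,
# so the optimizer works on the variance parameters only, on an
# unconstrained scale (log variances, atanh-scaled correlations).

centered_columns <- c("participant_id", "y_j", "m_prev", "m_within",
                      "m_between", "t_within", "t_between",
                      "tprev_within", "tprev_between")

beta_names_msem <- c("intercept_m", "a", "t_between_m",
                     "intercept_y", "b", "c_prime", "t_between_y",
                     "m_between_y")

build_design <- function(data, spec) {
  missing_cols <- setdiff(centered_columns, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("fit_mediation: centered dataset lacks column(s): ",
                 paste(missing_cols, collapse = ", "),
                 " (run build_lagged_dataset() |> center_within_between())"),
          class = "lagmed_input_error")
  }
  d <- dplyr::arrange(data, .data$participant_id)
  n <- nrow(d)
  pid <- as.integer(factor(d$participant_id, levels = unique(d$participant_id)))
  ngrp <- max(pid)

  zero <- numeric(n)
  one <- rep(1, n)
  Xm <- cbind(one, d$tprev_within, d$tprev_between, zero, zero, zero, zero, zero)
  Xy <- cbind(zero, zero, zero, one, d$m_within, d$t_within, d$t_between,
              d$m_between)

  re_names <- c("int_m",
                if ("a" %in% spec$random_paths) "a_dev",
                "int_y",
                if ("cprime" %in% spec$random_paths) "c_dev",
                if (spec$b_random) "b_dev")
  zcol <- function(mcol, ycol) c(mcol, ycol)
  Zparts <- list(
    int_m = zcol(one, zero),
    a_dev = zcol(d$tprev_within, zero),
    int_y = zcol(zero, one),
    c_dev = zcol(zero, d$t_within),
    b_dev = zcol(zero, d$m_within))
  Zfull <- do.call(cbind, Zparts[re_names])

  cov_pairs <- NULL
  cov_names <- character(0)
  if (all(c("a_dev", "c_dev") %in% re_names) && spec$estimate_random_correlation) {
    cov_pairs <- rbind(cov_pairs, match(c("a_dev", "c_dev"), re_names))
    cov_names <- c(cov_names, "cor_ac")
  }
  if (spec$b_random && "a_dev" %in% re_names) {
    cov_pairs <- rbind(cov_pairs, match(c("a_dev", "b_dev"), re_names))
    cov_names <- c(cov_names, "cor_ab")
  }

  # stack M block then Y block within each participant
  pid2 <- rep(pid, 2)
  block <- rep(0:1, each = n)
  ord <- order(pid2, block, rep(seq_len(n), 2))
  y_full <- c(d$m_prev, d$y_j)[ord]
  X_full <- rbind(Xm, Xy)[ord, , drop = FALSE]
  Z_full <- Zfull[ord, , drop = FALSE]
  eq <- block[ord]
  pid_sorted <- pid2[ord]

  pos <- integer(2 * n)
  pos[ord] <- seq_len(2 * n)
  pair_row <- integer(2 * n)
  pair_row[pos[seq_len(n)]] <- pos[n + seq_len(n)] - 1L
  pair_row[pos[n + seq_len(n)]] <- pos[seq_len(n)] - 1L

  grp_start <- which(!duplicated(pid_sorted))
  grp_end <- c(grp_start[-1] - 1L, 2L * n)

  if (any(!is.finite(y_full))) {
    abort("fit_mediation: centered dataset contains missing responses",
          class = "lagmed_input_error")
  }

  list(y = y_full, X = X_full, Z = Z_full,
       grp_start = as.integer(grp_start - 1L),
       grp_end = as.integer(grp_end - 1L),
       eq = eq, pair_row = as.integer(pair_row),
       beta_names = beta_names_msem, re_names = re_names,
       cov_pairs = cov_pairs, cov_names = cov_names,
       cross_resid = spec$estimate_cross_equation_residual_covariance,
       n_participants = ngrp, n_rows = n, data_sorted = d)
}

theta_names_design <- function(design) {
  c(paste0("log_var_", design$re_names),
    design$cov_names,
    "log_sigma2_m", "log_sigma2_y",
    if (design$cross_resid) "cor_resid_my")
}

# unconstrained theta -> (G, per-row residual variance, residual covariance)
theta_to_struct <- function(theta, design) {
  q <- length(design$re_names)
  ncov <- length(design$cov_names)
  sds <- exp(0.5 * theta[seq_len(q)])
  C <- diag(q)
  if (ncov > 0) {
    for (k in seq_len(ncov)) {
      i <- design$cov_pairs[k, 1]; j <- design$cov_pairs[k, 2]
      C[i, j] <- C[j, i] <- tanh(theta[q + k])
    }
  }
  G <- diag(sds, q) %*% C %*% diag(sds, q)
  s2m <- exp(theta[q + ncov + 1])
  s2y <- exp(theta[q + ncov + 2])
  resid_var <- ifelse(design$eq == 0, s2m, s2y)
  resid_cov <- if (design$cross_resid) {
    tanh(theta[q + ncov + 3]) * sqrt(s2m * s2y)
  } else 0
  list(G = G, resid_var = resid_var, resid_cov = resid_cov,
       s2m = s2m, s2y = s2y)
}

.nll_penalty <- 1e10

nll_theta <- function(theta, design, want_full = FALSE) {
  st <- theta_to_struct(theta, design)
  out <- msem_nll_engine(design$y, design$X, design$Z,
                         design$grp_start, design$grp_end,
                         st$G, st$resid_var, design$pair_row, st$resid_cov,
                         TRUE, numeric(ncol(design$X)), want_full)
  if (!isTRUE(out$ok) || !is.finite(out$nll)) {
    if (want_full) return(list(ok = FALSE, nll = .nll_penalty))
    return(.nll_penalty)
  }
  if (want_full) out else out$nll
}

#' Exact negative log-likelihood of the mediation model
#'
#' Evaluates minus the Gaussian marginal log-likelihood of the two-equation
#' model at an explicit parameter vector (fixed effects followed by the
#' unconstrained variance parameters). Participants are independent; per
#' participant the stacked (process, outcome) response vector is multivariate
#' normal with mean from the fixed effects and covariance built from the
#' random effects plus residual variances. Variance parameters enter on an
#' unconstrained scale (log variances, atanh-scaled correlations), which
#' guarantees a positive-definite covariance; degenerate proposals return a
#' large penalized value.
#'
#' @param params Numeric vector `c(beta, theta)`; see
#'   [msem_parameter_names()] for the layout.
#' @param data Centered dataset from [center_within_between()].
#' @param spec A [mediation_spec].
#' @return A single number (the negative log-likelihood).
#' @export
negative_log_likelihood <- function(params, data, spec) {
  design <- build_design(data, spec)
  p <- length(design$beta_names)
  n_theta <- length(theta_names_design(design))
  if (length(params) != p + n_theta) {
    abort(paste0("negative_log_likelihood: expected ", p + n_theta,
                 " parameters (", p, " fixed effects + ", n_theta,
                 " variance parameters)"),
          class = "lagmed_input_error")
  }
  beta <- params[seq_len(p)]
  theta <- params[p + seq_len(n_theta)]
  st <- theta_to_struct(theta, design)
  out <- msem_nll_engine(design$y, design$X, design$Z,
                         design$grp_start, design$grp_end,
                         st$G, st$resid_var, design$pair_row, st$resid_cov,
                         FALSE, beta, FALSE)
  if (!isTRUE(out$ok) || !is.finite(out$nll)) return(.nll_penalty)
  out$nll
}

#' Parameter layout of the mediation likelihood
#'
#' @inheritParams negative_log_likelihood
#' @return Character vector naming, in order, the fixed effects and the
#'   unconstrained variance parameters expected by
#'   [negative_log_likelihood()].
#' @export
msem_parameter_names <- function(data, spec) {
  design <- build_design(data, spec)
  c(design$beta_names, theta_names_design(design))
}

# deterministic starting values: per-participant least squares moments
start_theta <- function(design) {
  d <- design$data_sorted
  groups <- split(seq_len(nrow(d)), d$participant_id)

  slope_of <- function(y, x) {
    vx <- var(x)
    if (length(y) >= 2 && is.finite(vx) && vx > 0) {
      cov(x, y) / vx
    } else NA_real_
  }
  a_slopes <- vapply(groups, function(ix)
    slope_of(d$m_prev[ix], d$tprev_within[ix]), numeric(1))
  c_slopes <- vapply(groups, function(ix)
    slope_of(d$y_j[ix], d$t_within[ix]), numeric(1))
  m_means <- vapply(groups, function(ix) mean(d$m_prev[ix]), numeric(1))
  y_means <- vapply(groups, function(ix) mean(d$y_j[ix]), numeric(1))

  safe_var <- function(x, floor = 1e-8) {
    v <- var(x[is.finite(x)])
    if (!is.finite(v) || v < floor) floor else v
  }
  # per-participant slope variance over-states the random-slope variance
  # (it includes least-squares noise); halving is a serviceable start
  var_a0 <- safe_var(a_slopes) * 0.5
  var_c0 <- safe_var(c_slopes) * 0.5
  var_int_m0 <- safe_var(m_means)
  var_int_y0 <- safe_var(y_means)

  a0 <- mean(a_slopes[is.finite(a_slopes)])
  if (!is.finite(a0)) a0 <- 0
  resid_m <- d$m_prev - (m_means[match(d$participant_id, names(groups))] +
                           a0 * d$tprev_within)
  s2m0 <- max(var(resid_m) * 0.7, 1e-8)
  c0 <- mean(c_slopes[is.finite(c_slopes)])
  if (!is.finite(c0)) c0 <- 0
  resid_y <- d$y_j - (y_means[match(d$participant_id, names(groups))] +
                        c0 * d$t_within)
  s2y0 <- max(var(resid_y) * 0.7, 1e-8)

  start_map <- c(int_m = var_int_m0, a_dev = var_a0,
                 int_y = var_int_y0, c_dev = var_c0, b_dev = var_c0)
  theta <- c(log(start_map[design$re_names]),
             rep(0, length(design$cov_names)),
             log(s2m0), log(s2y0),
             if (design$cross_resid) 0)
  setNames(as.numeric(theta), theta_names_design(design))
}

#' Fit the lagged multilevel mediation model
#'
#' Maximizes the exact Gaussian marginal likelihood (see
#' [negative_log_likelihood()]) by quasi-Newton (`L-BFGS-B`) iteration over
#' the unconstrained variance parameters, with the fixed effects profiled
#' out by generalized least squares. Starting values are deterministic
#' (per-participant least-squares slopes and residual moments), so refitting
#' the same data reproduces the same estimates, and estimates do not depend
#' on participant ordering.
#'
#' Fixed-effect standard errors are model-based GLS SEs,
#' `(sum_i X_i' V_i^-1 X_i)^-1`, evaluated at the variance-parameter optimum
#' (the convention of mixed-model software); `se_method = "sandwich"` in the
#' spec replaces them with cluster-robust (participant-level) sandwich SEs.
#' Variance-parameter SEs come from a numerical Hessian on the unconstrained
#' scale.
#'
#' @param data Centered dataset from [center_within_between()].
#' @param spec A [mediation_spec].
#' @param control A [fit_control] list.
#' @return An object of class `mediation_fit`: path estimates (`a`, `b`,
#'   `c_prime`, between-level coefficients), random-slope variances and
#'   covariance, residual variances, SEs, log-likelihood, convergence flag,
#'   and bookkeeping (`n_participants`, `n_rows`, the model spec). Use [tidy()],
#'   [glance()], [wald_tests()], [indirect_effect()] on the result.
#' @export
fit_mediation <- function(data, spec, control = fit_control()) {
  stopifnot(inherits(spec, "mediation_spec"), inherits(control, "fit_control"))
  design <- build_design(data, spec)
  if (design$n_participants < 2) {
    abort("fit_mediation: need at least 2 participants to support the random effects",
          class = "lagmed_input_error")
  }
  theta0 <- start_theta(design)
  n_theta <- length(theta0)
  q <- length(design$re_names)
  ncov <- length(design$cov_names)
  lower <- c(rep(-35, q), rep(-4, ncov), rep(-35, 2),
             if (design$cross_resid) -4)
  upper <- -lower

  opt <- optim(theta0, nll_theta, design = design,
               method = "L-BFGS-B", lower = lower, upper = upper,
               control = list(maxit = control$maxit, factr = control$factr,
                              pgtol = control$pgtol))
  theta_hat <- opt$par
  full <- nll_theta(theta_hat, design, want_full = TRUE)
  if (!isTRUE(full$ok)) {
    abort("fit_mediation: likelihood degenerate at the reported optimum",
          class = "lagmed_fit_error")
  }
  beta <- setNames(as.numeric(full$beta), design$beta_names)
  A <- full$XtViX
  vcov_beta <- tryCatch(solve(A), error = function(e) NULL)
  if (spec$se_method == "sandwich" && !is.null(vcov_beta)) {
    # cluster-level GLS scores at the optimum
    st <- theta_to_struct(theta_hat, design)
    sc <- msem_nll_engine(design$y, design$X, design$Z,
                          design$grp_start, design$grp_end,
                          st$G, st$resid_var, design$pair_row, st$resid_cov,
                          FALSE, as.numeric(beta), TRUE)$scores
    meat <- tcrossprod(sc)
    vcov_beta <- vcov_beta %*% meat %*% vcov_beta
  }
  if (!is.null(vcov_beta)) {
    dimnames(vcov_beta) <- list(design$beta_names, design$beta_names)
  }

  vcov_theta <- NULL
  if (control$variance_hessian) {
    H <- tryCatch(optimHess(theta_hat, nll_theta, design = design),
                  error = function(e) NULL)
    if (!is.null(H)) {
      vcov_theta <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vcov_theta)) {
        dimnames(vcov_theta) <- list(names(theta0), names(theta0))
      }
    }
  }

  st <- theta_to_struct(theta_hat, design)
  vars <- setNames(exp(theta_hat[seq_len(q)]),
                   paste0("var_", design$re_names))
  cov_ac <- if ("cor_ac" %in% design$cov_names) {
    st$G[design$cov_pairs[match("cor_ac", design$cov_names), 1],
         design$cov_pairs[match("cor_ac", design$cov_names), 2]]
  } else NA_real_
  sigma_ab <- if ("cor_ab" %in% design$cov_names) {
    st$G[design$cov_pairs[match("cor_ab", design$cov_names), 1],
         design$cov_pairs[match("cor_ab", design$cov_names), 2]]
  } else 0

  structure(
    list(beta = beta,
         vcov_beta = vcov_beta,
         theta = setNames(theta_hat, names(theta0)),
         vcov_theta = vcov_theta,
         G = st$G,
         random_variances = vars,
         cov_ac = cov_ac,
         sigma_ab = sigma_ab,
         sigma2_m = st$s2m,
         sigma2_y = st$s2y,
         logLik = -opt$value,
         converged = opt$convergence == 0,
         optim_message = opt$message,
         n_participants = design$n_participants,
         n_rows = design$n_rows,
         spec = spec,
         control = control,
         design_names = list(beta = design$beta_names,
                             theta = names(theta0),
                             re = design$re_names)),
    class = "mediation_fit")
}

#' @export
coef.mediation_fit <- function(object, ...) object$beta

#' @export
logLik.mediation_fit <- function(object, ...) {
  structure(object$logLik,
            df = length(object$beta) + length(object$theta),
            nobs = 2 * object$n_rows, class = "logLik")
}

#' @export
vcov.mediation_fit <- function(object, ...) object$vcov_beta

#' @export
print.mediation_fit <- function(x, digits = 3, ...) {
  cat("Lagged multilevel mediation fit",
      if (x$spec$reversed) "(reversed direction)" else "", "\n")
  cat("  process:", x$spec$process_var, " outcome:", x$spec$outcome_var, "\n")
  cat("  participants:", x$n_participants, " lagged rows:", x$n_rows, "\n")
  cat("  logLik:", format(x$logLik, digits = 8),
      " converged:", x$converged, "\n\n")
  paths <- c(a = unname(x$beta["a"]), b = unname(x$beta["b"]),
             c_prime = unname(x$beta["c_prime"]))
  print(round(paths, digits))
  cat("\nRandom-effect variances:\n")
  print(signif(x$random_variances, digits))
  if (is.finite(x$cov_ac)) {
    cat("cov(a, c'):", signif(x$cov_ac, digits), "\n")
  }
  cat("Residual variances: sigma2_m =", signif(x$sigma2_m, digits),
      ", sigma2_y =", signif(x$sigma2_y, digits), "\n")
  invisible(x)
}

#' Random-intercept-only variance decomposition via the package likelihood
#'
#' Fits `value ~ 1 + (1 | participant)` by the same marginal-likelihood
#' engine used for the full mediation model. Serves as the internal
#' counterpart of [compute_icc()] (which delegates to lme4), so the two
#' routes can be compared on identical data.
#'
#' @param data Long-format data frame with `participant_id` and the variable.
#' @param var Name of the variable column.
#' @return List with `icc`, `var_between`, `var_within`, `logLik`,
#'   `converged`.
#' @export
fit_random_intercept <- function(data, var) {
  stopifnot(is.data.frame(data), var %in% names(data))
  d <- data[!is.na(data[[var]]), ]
  y <- d[[var]]
  pid <- as.integer(factor(d$participant_id, levels = unique(d$participant_id)))
  ord <- order(pid)
  y <- y[ord]; pid <- pid[ord]
  n <- length(y)
  grp_start <- which(!duplicated(pid)) - 1L
  grp_end <- c(grp_start[-1] - 1L, n - 1L)
  X <- matrix(1, n, 1)
  Z <- matrix(1, n, 1)
  fn <- function(theta) {
    out <- msem_nll_engine(y, X, Z, grp_start, as.integer(grp_end),
                           matrix(exp(theta[1]), 1, 1),
                           rep(exp(theta[2]), n),
                           rep(-1L, n), 0, TRUE, 0, FALSE)
    if (!isTRUE(out$ok) || !is.finite(out$nll)) return(.nll_penalty)
    out$nll
  }
  v0 <- var(y)
  opt <- optim(log(c(v0 / 2, v0 / 2)), fn, method = "L-BFGS-B",
               lower = c(-35, -35), upper = c(35, 35),
               control = list(factr = 1e5, pgtol = 1e-8, maxit = 500))
  vb <- exp(opt$par[1]); vw <- exp(opt$par[2])
  list(icc = vb / (vb + vw), var_between = vb, var_within = vw,
       logLik = -opt$value, converged = opt$convergence == 0)
}
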