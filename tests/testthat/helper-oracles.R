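# Independent oracles and small fixture builders, deliberately written
# without reusing the package's computational path.

# Coefficient alpha straight from the covariance matrix of complete rows:
# k/(k-1) * (1 - tr(S) / sum(S)).
alpha_covmat_oracle <- function(items) {
  x <- as.matrix(items)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  S <- stats::cov(x)
  k <- ncol(x)
  k / (k - 1) * (1 - sum(diag(S)) / sum(S))
}

# Naive double-loop lagging rule: for each occasion with an observed
# outcome, scan backwards for the most recent earlier occasion (strictly
# earlier day) with an observed process value.
lag_bruteforce_oracle <- function(df, process, outcome) {
  out <- list()
  for (pid in unique(df$participant_id)) {
    d <- df[df$participant_id == pid, ]
    d <- d[order(d$session_index), ]
    for (j in seq_len(nrow(d))[-1]) {
      if (is.na(d[[outcome]][j])) next
      partner <- NA_integer_
      for (k in rev(seq_len(j - 1))) {
        if (!is.na(d[[process]][k]) &&
            d$days_since_first_session[k] < d$days_since_first_session[j]) {
          partner <- k
          break
        }
      }
      if (is.na(partner)) next
      out[[length(out) + 1]] <- data.frame(
        participant_id = pid,
        session_index = d$session_index[j],
        t_j = d$days_since_first_session[j],
        y_j = d[[outcome]][j],
        m_prev = d[[process]][partner],
        t_prev = d$days_since_first_session[partner])
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(res)
  res$gap <- res$t_j - res$t_prev
  res
}

# Dense multivariate-normal evaluation of the mediation likelihood: builds
# each participant's full joint covariance Z G Z' + R and evaluates the
# Gaussian density directly via a Cholesky factor. Parameter layout follows
# the documented contract (fixed effects, then log variances, correlations,
# log residual variances, optional residual correlation).
dense_nll_oracle <- function(params, data, spec) {
  d <- data[order(data$participant_id), ]
  beta <- params[1:8]
  re_names <- c("int_m",
                if ("a" %in% spec$random_paths) "a_dev",
                "int_y",
                if ("cprime" %in% spec$random_paths) "c_dev",
                if (spec$b_random) "b_dev")
  q <- length(re_names)
  cov_names <- c(
    if (all(c("a_dev", "c_dev") %in% re_names) &&
        spec$estimate_random_correlation) "cor_ac",
    if (spec$b_random && "a_dev" %in% re_names) "cor_ab")
  theta <- params[-(1:8)]
  sds <- exp(0.5 * theta[seq_len(q)])
  C <- diag(q)
  rownames(C) <- colnames(C) <- re_names
  idx <- q
  if ("cor_ac" %in% cov_names) {
    idx <- idx + 1
    C["a_dev", "c_dev"] <- C["c_dev", "a_dev"] <- tanh(theta[idx])
  }
  if ("cor_ab" %in% cov_names) {
    idx <- idx + 1
    C["a_dev", "b_dev"] <- C["b_dev", "a_dev"] <- tanh(theta[idx])
  }
  G <- diag(sds, q) %*% C %*% diag(sds, q)
  s2m <- exp(theta[idx + 1])
  s2y <- exp(theta[idx + 2])
  rho_my <- if (spec$estimate_cross_equation_residual_covariance) {
    tanh(theta[idx + 3])
  } else 0

  nll <- 0
  for (pid in unique(d$participant_id)) {
    di <- d[d$participant_id == pid, ]
    n <- nrow(di)
    one <- rep(1, n); zero <- rep(0, n)
    Xm <- cbind(one, di$tprev_within, di$tprev_between,
                zero, zero, zero, zero, zero)
    Xy <- cbind(zero, zero, zero, one, di$m_within, di$t_within,
                di$t_between, di$m_between)
    X <- rbind(Xm, Xy)
    Zcols <- list(int_m = c(one, zero), a_dev = c(di$tprev_within, zero),
                  int_y = c(zero, one), c_dev = c(zero, di$t_within),
                  b_dev = c(zero, di$m_within))
    Z <- do.call(cbind, Zcols[re_names])
    R <- diag(c(rep(s2m, n), rep(s2y, n)))
    if (rho_my != 0) {
      for (i in seq_len(n)) {
        R[i, n + i] <- R[n + i, i] <- rho_my * sqrt(s2m * s2y)
      }
    }
    V <- Z %*% G %*% t(Z) + R
    r <- c(di$m_prev, di$y_j) - X %*% beta
    L <- chol(V)
    logdet <- 2 * sum(log(diag(L)))
    quad <- sum(backsolve(L, r, transpose = TRUE)^2)
    nll <- nll + 0.5 * (2 * n * log(2 * pi) + logdet + quad)
  }
  nll
}

# small deterministic noise-free cohort lying exactly on the generating
# lines (var_a = var_c = 0); irregular within-participant gaps break the
# collinearity between the lagged process and time
noise_free_cohort <- function(a = -0.01, b = 0.8, c_prime = -0.03,
                              n_participants = 5) {
  gaps <- list(c(5, 9, 6, 12, 8), c(7, 4, 11, 6, 9), c(6, 10, 5, 8, 12),
               c(8, 5, 9, 11, 4), c(9, 7, 12, 5, 6))
  rows <- lapply(seq_len(n_participants), function(i) {
    t <- c(0, cumsum(gaps[[((i - 1) %% 5) + 1]]))
    int_m <- 4 + 0.5 * i
    int_y <- 18 + i
    m <- int_m + a * t
    y <- int_y + c_prime * t
    y[-1] <- y[-1] + b * (m[-length(m)] - mean(m))
    data.frame(participant_id = i, session_index = seq_along(t),
               days_since_first_session = t, m = m, y = y)
  })
  do.call(rbind, rows)
}

# random small centered instances for likelihood-equivalence checks
random_centered_instance <- function(seed, n_participants = 4,
                                     max_rows = 4) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_participants), function(i) {
      n <- sample(2:max_rows, 1)
      t <- sort(sample(0:60, n))
      data.frame(
        participant_id = i,
        session_index = seq_len(n),
        t_j = t + 1,
        t_prev = t,
        m_prev = rnorm(n, 5, 1.5),
        y_j = rnorm(n, 20, 4))
    })
    df <- do.call(rbind, rows)
    df$gap <- df$t_j - df$t_prev
    center_within_between(tibble::as_tibble(df))
  })
}
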