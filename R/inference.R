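#' Percent mediation
#'
#' Share of the total time-to-outcome effect carried through the process
#' variable: `100 * (ab + sigma_ab) / (ab + c_prime + sigma_ab)`. When path b
#' is fixed across participants the slope covariance `sigma_ab` is
#' structurally zero and the expression reduces to `100 * ab / (ab + c')`.
#'
#' Values outside \[0, 100\] (possible when the indirect and direct paths
#' oppose in sign) are returned as computed — not clipped — and flagged; a
#' zero denominator yields `NaN` flagged `"zero_denominator"`.
#'
#' @param ab Indirect-effect estimate(s) (`a * b`).
#' @param c_prime Direct-path estimate(s).
#' @param sigma_ab Covariance of the random a and b slopes (default 0, the
#'   fixed-b case).
#' @return Numeric vector with attribute `flag` (per element: `"ok"`,
#'   `"out_of_range"`, or `"zero_denominator"`).
#' @examples
#' percent_mediation(-0.011 * 1.922, -0.029)  # ~42
#' @export
percent_mediation <- function(ab, c_prime, sigma_ab = 0) {
  denom <- ab + c_prime + sigma_ab
  pm <- ifelse(denom == 0, NaN, 100 * (ab + sigma_ab) / denom)
  flag <- dplyr::case_when(
    denom == 0 ~ "zero_denominator",
    pm < 0 | pm > 100 ~ "out_of_range",
    TRUE ~ "ok")
  structure(pm, flag = flag)
}

#' Indirect effect and percent mediation from a fitted model
#'
#' Computes `ab = a * b + sigma_ab` (with `sigma_ab = 0` under fixed b), a
#' first-order delta-method standard error from the joint covariance of
#' (a, b), a confidence interval (delta-method normal by default, or Monte
#' Carlo by sampling (a, b) from their asymptotic joint normal), and the
#' percent mediation.
#'
#' @param fit A [fit_mediation()] result.
#' @param level Confidence level (default 0.95).
#' @param ci_method `"delta"` or `"montecarlo"`.
#' @param n_mc Monte Carlo draws (when `ci_method = "montecarlo"`).
#' @param seed Seed for the Monte Carlo interval (required for
#'   reproducibility when `ci_method = "montecarlo"`).
#' @return One-row tibble: `ab`, `se_ab`, `ci_lower`, `ci_upper`,
#'   `sigma_ab`, `c_prime`, `pm`, `pm_flag`, `converged`.
#' @export
indirect_effect <- function(fit, level = 0.95,
                            ci_method = c("delta", "montecarlo"),
                            n_mc = 10000, seed = 1) {
  stopifnot(inherits(fit, "mediation_fit"))
  ci_method <- match.arg(ci_method)
  if (!isTRUE(fit$converged)) {
    warn("indirect_effect: fit did not converge; results flagged")
  }
  a <- unname(fit$beta["a"])
  b <- unname(fit$beta["b"])
  c_prime <- unname(fit$beta["c_prime"])
  sigma_ab <- fit$sigma_ab
  ab <- a * b + sigma_ab

  se_ab <- NA_real_
  ci <- c(NA_real_, NA_real_)
  V <- fit$vcov_beta
  if (!is.null(V)) {
    va <- V["a", "a"]; vb <- V["b", "b"]; vab <- V["a", "b"]
    se_ab <- sqrt(b^2 * va + a^2 * vb + 2 * a * b * vab)
    zc <- qnorm(1 - (1 - level) / 2)
    if (ci_method == "delta") {
      ci <- ab + c(-1, 1) * zc * se_ab
    } else {
      Sig <- V[c("a", "b"), c("a", "b")]
      L <- chol(Sig)
      draws <- withr::with_seed(seed, {
        e <- matrix(rnorm(2 * n_mc), n_mc, 2) %*% L
        (a + e[, 1]) * (b + e[, 2]) + sigma_ab
      })
      ci <- unname(quantile(draws, c((1 - level) / 2, 1 - (1 - level) / 2)))
    }
  }

  pm <- percent_mediation(ab, c_prime, sigma_ab)
  pm_flag <- attr(pm, "flag")
  tibble::tibble(
    ab = ab, se_ab = se_ab, ci_lower = ci[1], ci_upper = ci[2],
    sigma_ab = sigma_ab, c_prime = c_prime,
    pm = as.numeric(pm), pm_flag = pm_flag,
    converged = fit$converged)
}

#' Wald tests for all free parameters
#'
#' Fixed effects are tested on their natural scale with model-based (or
#' sandwich, when the model spec requests them) SEs; variance parameters are tested on the
#' unconstrained (log-variance / atanh-correlation) scale, on which the
#' normal approximation is defensible — a caveat recorded in the `scale`
#' column. `z = estimate / SE`, two-sided normal p, CI `estimate +/- 1.96 SE`.
#'
#' @param fit A [fit_mediation()] result.
#' @param level Confidence level (default 0.95).
#' @return Tibble with `term`, `estimate`, `se`, `statistic`, `p.value`,
#'   `conf.low`, `conf.high`, `scale`, `flagged` (TRUE when the SE is
#'   unavailable).
#' @export
wald_tests <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "mediation_fit"))
  zc <- qnorm(1 - (1 - level) / 2)
  se_beta <- if (!is.null(fit$vcov_beta)) {
    sqrt(pmax(diag(fit$vcov_beta), 0))
  } else rep(NA_real_, length(fit$beta))
  fixed <- tibble::tibble(
    term = names(fit$beta),
    estimate = as.numeric(fit$beta),
    se = as.numeric(se_beta),
    scale = "natural")
  se_theta <- if (!is.null(fit$vcov_theta)) {
    sqrt(pmax(diag(fit$vcov_theta), 0))
  } else rep(NA_real_, length(fit$theta))
  vpars <- tibble::tibble(
    term = names(fit$theta),
    estimate = as.numeric(fit$theta),
    se = as.numeric(se_theta),
    scale = "unconstrained")
  dplyr::bind_rows(fixed, vpars) |>
    dplyr::mutate(
      statistic = .data$estimate / .data$se,
      p.value = 2 * pnorm(-abs(.data$statistic)),
      conf.low = .data$estimate - zc * .data$se,
      conf.high = .data$estimate + zc * .data$se,
      flagged = !is.finite(.data$se)) |>
    dplyr::select("term", "estimate", "se", "statistic", "p.value",
                  "conf.low", "conf.high", "scale", "flagged")
}

#' @rdname fit_mediation
#' @param x A `mediation_fit` object.
#' @param effects Which parameter block(s) to return: `"fixed"`,
#'   `"variance"`, or both.
#' @param ... Unused.
#' @method tidy mediation_fit
#' @export
tidy.mediation_fit <- function(x, effects = c("fixed", "variance"), ...) {
  effects <- match.arg(effects, several.ok = TRUE)
  out <- wald_tests(x)
  keep <- character(0)
  if ("fixed" %in% effects) keep <- c(keep, "natural")
  if ("variance" %in% effects) keep <- c(keep, "unconstrained")
  dplyr::filter(out, .data$scale %in% keep)
}

#' @rdname fit_mediation
#' @method glance mediation_fit
#' @export
glance.mediation_fit <- function(x, ...) {
  k <- length(x$beta) + length(x$theta)
  tibble::tibble(
    logLik = x$logLik,
    AIC = -2 * x$logLik + 2 * k,
    BIC = -2 * x$logLik + log(2 * x$n_rows) * k,
    n_participants = x$n_participants,
    n_rows = x$n_rows,
    converged = x$converged)
}
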