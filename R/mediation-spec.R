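#' Specify a lagged multilevel mediation model
#'
#' Describes the two-equation model in which time-in-treatment drives the
#' process variable (path a, random across participants), the lagged
#' within-person process drives the outcome (path b, fixed by default), and
#' time retains a direct effect on the outcome (path c', random).
#'
#' @param process_var Name of the process (mediator) score column.
#' @param outcome_var Name of the outcome score column.
#' @param reversed Logical flag marking a direction-probing model in which
#'   the roles were swapped (set by [reverse_model()]).
#' @param random_paths Subset of `c("a", "cprime")` allowed to vary across
#'   participants (default both, as in the reference design).
#' @param b_random Estimate a random slope for path b as well (default
#'   `FALSE`; when `FALSE` the slope covariance `sigma_ab` is structurally 0
#'   in percent-mediation arithmetic).
#' @param estimate_random_correlation Estimate the correlation between the
#'   random a and c' slopes (default `TRUE`).
#' @param estimate_cross_equation_residual_covariance Allow a residual
#'   covariance between a row's process and outcome responses (default
#'   `FALSE`, the two-equation factorization implied by the lag).
#' @param se_method `"observed_information"` (model-based, default) or
#'   `"sandwich"` (cluster-robust) standard errors for the fixed effects.
#' @return A list of class `mediation_spec`.
#' @export
mediation_spec <- function(process_var, outcome_var,
                           reversed = FALSE,
                           random_paths = c("a", "cprime"),
                           b_random = FALSE,
                           estimate_random_correlation = TRUE,
                           estimate_cross_equation_residual_covariance = FALSE,
                           se_method = c("observed_information", "sandwich")) {
  stopifnot(is.character(process_var), is.character(outcome_var),
            process_var != outcome_var)
  if (!all(random_paths %in% c("a", "cprime"))) {
    abort("mediation_spec: random_paths must be a subset of c('a', 'cprime')",
          class = "lagmed_input_error")
  }
  structure(
    list(process_var = process_var,
         outcome_var = outcome_var,
         reversed = isTRUE(reversed),
         random_paths = random_paths,
         b_random = isTRUE(b_random),
         estimate_random_correlation = isTRUE(estimate_random_correlation),
         estimate_cross_equation_residual_covariance =
           isTRUE(estimate_cross_equation_residual_covariance),
         se_method = match.arg(se_method)),
    class = "mediation_spec")
}

#' Swap mediator and outcome roles
#'
#' Returns the direction-probing ("reversed") counterpart of a model spec:
#' process and outcome variables exchanged, the `reversed` flag toggled, all
#' structural options preserved. Applying it twice restores the original
#' roles.
#'
#' @param spec A [mediation_spec] object.
#' @return A [mediation_spec] with roles swapped.
#' @export
reverse_model <- function(spec) {
  stopifnot(inherits(spec, "mediation_spec"))
  out <- spec
  out$process_var <- spec$outcome_var
  out$outcome_var <- spec$process_var
  out$reversed <- !spec$reversed
  out
}

#' @export
print.mediation_spec <- function(x, ...) {
  cat("<mediation_spec>", if (x$reversed) "(reversed)" else "", "\n")
  cat("  process (mediator):", x$process_var, "\n")
  cat("  outcome:           ", x$outcome_var, "\n")
  cat("  random paths:      ", paste(x$random_paths, collapse = ", "),
      if (x$b_random) "+ b" else "", "\n")
  cat("  cor(a, c') estimated:", x$estimate_random_correlation, "\n")
  cat("  SEs:", x$se_method, "\n")
  invisible(x)
}

#' Convergence and optimizer settings for [fit_mediation()]
#'
#' @param maxit Maximum optimizer iterations (default 500).
#' @param factr,pgtol `L-BFGS-B` stopping controls: relative
#'   log-likelihood change below `factr * .Machine$double.eps` (the default
#'   corresponds to a relative change of about 1e-8) and projected gradient
#'   norm below `pgtol`.
#' @param variance_hessian Compute the numerical Hessian of the profiled
#'   likelihood over the variance parameters (needed for variance-parameter
#'   SEs; can be disabled in large simulation studies where only the fixed
#'   effects are examined).
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(maxit = 500, factr = 4.5e7, pgtol = 1e-5,
                        variance_hessian = TRUE) {
  structure(list(maxit = maxit, factr = factr, pgtol = pgtol,
                 variance_hessian = isTRUE(variance_hessian)),
            class = "fit_control")
}
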