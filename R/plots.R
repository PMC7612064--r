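# ggplot2 displays for cohorts, fits, and recovery studies.

#' Spaghetti plot of session-by-session trajectories
#'
#' @param data Scored long-format data frame.
#' @param var Score column to plot.
#' @param n_highlight Number of participants drawn with emphasised lines
#'   (the rest form a grey background).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(data, var, n_highlight = 12) {
  stopifnot(var %in% names(data))
  ids <- unique(data$participant_id)
  hi <- ids[seq_len(min(n_highlight, length(ids)))]
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data$days_since_first_session, y = .data[[var]],
    group = .data$participant_id)) +
    ggplot2::geom_line(alpha = 0.15, colour = "grey40", na.rm = TRUE) +
    ggplot2::geom_line(
      data = data[data$participant_id %in% hi, ],
      ggplot2::aes(colour = factor(.data$participant_id)),
      linewidth = 0.6, na.rm = TRUE, show.legend = FALSE) +
    ggplot2::labs(x = "Days since first session", y = var,
                  title = paste("Session-by-session", var)) +
    ggplot2::theme_minimal()
}

#' @rdname fit_mediation
#' @param object A `mediation_fit`.
#' @method autoplot mediation_fit
#' @export
autoplot.mediation_fit <- function(object, ...) {
  td <- tidy(object, effects = "fixed")
  td$term <- factor(td$term, levels = rev(td$term))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$conf.low, xmax = .data$conf.high)) +
    ggplot2::labs(
      x = "Estimate (95% CI)", y = NULL,
      title = paste0("Mediation paths: ", object$spec$process_var,
                     " → ", object$spec$outcome_var,
                     if (object$spec$reversed) " (reversed)" else "")) +
    ggplot2::theme_minimal()
}

#' @rdname run_pipeline
#' @param object A `mediation_report`.
#' @param ... Unused.
#' @method autoplot mediation_report
#' @export
autoplot.mediation_report <- function(object, ...) {
  ind <- object$indirect
  ggplot2::ggplot(ind, ggplot2::aes(
    x = .data$ab, y = .data$model, colour = .data$direction)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_lower, xmax = .data$ci_upper),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = "Indirect effect ab (95% CI)", y = NULL,
                  colour = NULL,
                  title = paste("Indirect effects:", object$sample_label)) +
    ggplot2::theme_minimal()
}
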