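#' Build the lagged modelling dataset
#'
#' For every assessment occasion j (from the second onwards) at which the
#' outcome is observed, pairs the outcome with the process variable at the
#' previous *available* assessment — the most recent earlier occasion with an
#' observed process value — and records the elapsed-days gap between the two.
#' A participant's first available occasion never contributes an outcome row,
#' and rows whose lag partner would be at the same day (zero gap) or beyond
#' `max_gap` are dropped.
#'
#' Irregular spacing is expected: the model consumes the actual day gaps, so
#' occasional missed weeks or monthly booster sessions simply widen `gap`.
#'
#' @param data Scored long-format data frame with columns `participant_id`,
#'   `session_index`, `days_since_first_session` (nondecreasing, first
#'   occasion 0) plus score columns.
#' @param process_var,outcome_var Names of the process (mediator) and outcome
#'   score columns.
#' @param max_gap Maximum allowed lag gap in days (default unlimited).
#' @return A tibble of lagged rows: `participant_id`, `session_index`,
#'   `t_j` (days at occasion j), `y_j`, `m_prev`, `t_prev`, `gap`.
#' @export
build_lagged_dataset <- function(data, process_var, outcome_var,
                                 max_gap = Inf) {
  stopifnot(is.data.frame(data))
  needed <- c("participant_id", "session_index", "days_since_first_session",
              process_var, outcome_var)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("build_lagged_dataset: column(s) not found: ",
                 paste(missing_cols, collapse = ", ")),
          class = "lagmed_input_error")
  }
  if (any(data$days_since_first_session < 0, na.rm = TRUE)) {
    abort("build_lagged_dataset: days_since_first_session must be >= 0",
          class = "lagmed_input_error")
  }

  d <- data |>
    dplyr::select(participant_id = "participant_id",
                  session_index = "session_index",
                  t = "days_since_first_session",
                  m = dplyr::all_of(process_var),
                  y = dplyr::all_of(outcome_var)) |>
    dplyr::arrange(.data$participant_id, .data$session_index)

  lag_one <- function(df) {
    n <- nrow(df)
    if (any(diff(df$t) < 0)) {
      abort("build_lagged_dataset: days_since_first_session must be nondecreasing",
            class = "lagmed_input_error")
    }
    if (n < 2) return(NULL)
    # eligible partners sit strictly before the tie-run of equal days that
    # contains occasion j; among those, take the latest with an observed
    # process value
    runs <- rle(df$t)
    run_start <- rep(cumsum(c(1L, utils::head(runs$lengths, -1L))),
                     runs$lengths)
    prev_obs <- cummax(ifelse(!is.na(df$m), seq_len(n), 0L))
    partner <- ifelse(run_start > 1L, prev_obs[pmax(run_start - 1L, 1L)], 0L)
    keep <- !is.na(df$y) & partner > 0L
    keep[1] <- FALSE
    t_prev <- ifelse(keep, df$t[pmax(partner, 1L)], NA_real_)
    keep <- keep & (df$t - t_prev) <= max_gap
    if (!any(keep)) return(NULL)
    tibble::tibble(
      participant_id = df$participant_id[keep],
      session_index = df$session_index[keep],
      t_j = df$t[keep], y_j = df$y[keep],
      m_prev = df$m[partner[keep]], t_prev = df$t[partner[keep]])
  }

  idx <- split(seq_len(nrow(d)), factor(d$participant_id,
                                        levels = unique(d$participant_id)))
  out <- dplyr::bind_rows(lapply(idx, function(ix) lag_one(d[ix, ])))
  if (nrow(out) == 0) {
    return(tibble::tibble(participant_id = d$participant_id[0],
                          session_index = d$session_index[0],
                          t_j = double(), y_j = double(),
                          m_prev = double(), t_prev = double(),
                          gap = double()))
  }
  dplyr::mutate(out, gap = .data$t_j - .data$t_prev)
}

#' Within/between (group-mean-centered) decomposition
#'
#' Disaggregates the lagged process variable and the time covariates into
#' within-person deviations and between-person means. Means are taken over
#' each participant's *lagged rows* (the records the model actually uses),
#' which keeps the reconstruction `m_within + m_between == m_prev` exact in
#' the fitted dataset. Both the outcome-side time `t_j` and the process-side
#' time `t_prev` are decomposed, since they enter different equations.
#'
#' @param rows Tibble of lagged rows from [build_lagged_dataset()].
#' @return The input augmented with `m_within`, `m_between`, `t_within`,
#'   `t_between`, `tprev_within`, `tprev_between`.
#' @export
center_within_between <- function(rows) {
  stopifnot(is.data.frame(rows),
            all(c("participant_id", "t_j", "t_prev", "m_prev") %in% names(rows)))
  rows |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(
      m_between = mean(.data$m_prev),
      m_within = .data$m_prev - .data$m_between,
      t_between = mean(.data$t_j),
      t_within = .data$t_j - .data$t_between,
      tprev_between = mean(.data$t_prev),
      tprev_within = .data$t_prev - .data$tprev_between) |>
    dplyr::ungroup()
}

#' Intraclass correlation of a session-by-session variable
#'
#' Proportion of variance attributable to between-participant differences,
#' estimated by maximum likelihood under a random-intercept-only model
#' (`value ~ 1 + (1 | participant_id)`). Used as the screening statistic that
#' justifies multilevel modelling.
#'
#' @param data Long-format data frame with `participant_id` and the variable.
#' @param var Name of the variable column.
#' @return ICC in \[0, 1\]; `NA` with attribute `flag = "degenerate"` when
#'   the variable has (numerically) zero total variance.
#' @export
compute_icc <- function(data, var) {
  stopifnot(is.data.frame(data), var %in% names(data))
  d <- data[!is.na(data[[var]]), c("participant_id", var)]
  names(d) <- c("participant_id", "value")
  counts <- table(d$participant_id)
  if (length(counts) < 2 || sum(counts >= 2) < 2) {
    abort("compute_icc: need >= 2 participants with >= 2 observations each",
          class = "lagmed_input_error")
  }
  if (var(d$value) <= .Machine$double.eps * max(1, mean(d$value)^2)) {
    return(structure(NA_real_, flag = "degenerate"))
  }
  fit <- lme4::lmer(value ~ 1 + (1 | participant_id), data = d, REML = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_between <- vc$vcov[vc$grp == "participant_id"]
  v_within <- vc$vcov[vc$grp == "Residual"]
  v_between / (v_between + v_within)
}
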