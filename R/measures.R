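#' Canonical SPWSS item labels
#'
#' The Social Phobia Weekly Summary Scale has six 0-8 items: four social
#' anxiety items (overall anxiety, avoidance, anticipatory worry, post-event
#' rumination) and two self-focused attention items (attention in general and
#' in difficult situations).
#'
#' @format A list with elements `anxiety` (4 labels) and `sfa` (2 labels).
#' @export
spwss_items <- list(
  anxiety = c("overall_anxiety", "avoidance", "anticipatory_worry",
              "post_event_rumination"),
  sfa = c("sfa_general", "sfa_difficult")
)

# share of a scale's items that must be answered before a prorated score is
# computed; below this the score is missing
.proration_threshold <- 0.75

prorated_score <- function(values, n_items, type = c("total", "mean")) {
  type <- match.arg(type)
  n_ans <- sum(!is.na(values))
  if (n_ans < ceiling(.proration_threshold * n_items)) {
    return(NA_real_)
  }
  m <- mean(values, na.rm = TRUE)
  if (type == "total") m * n_items else m
}

#' Score the Social Phobia Weekly Summary Scale
#'
#' Computes, for every assessment occasion, the 4-item social anxiety total
#' (range 0-32: sum of the non-attention items) and the 2-item self-focused
#' attention mean (range 0-8). Scores are prorated (mean of answered items
#' times item count) when at least 75% of a subscale's items are answered,
#' and missing otherwise.
#'
#' @param data Long-format data frame with one row per (occasion, item):
#'   an `item` column using the labels in [spwss_items], a numeric `value`
#'   column in 0-8, and any number of occasion-identifier columns
#'   (e.g. `participant_id`, `session_index`) which are carried through.
#' @param item,value Column names (strings) holding the item label and the
#'   response.
#'
#' @return A tibble with one row per occasion: the identifier columns plus
#'   `social_anxiety`, `sfa`, `n_items_social`, `n_items_sfa`.
#' @examples
#' d <- tidyr::expand_grid(participant_id = 1, session_index = 1,
#'                         item = unlist(spwss_items))
#' d$value <- c(6, 5, 5, 5, 5, 6)
#' score_spwss(d)
#' @export
score_spwss <- function(data, item = "item", value = "value") {
  stopifnot(is.data.frame(data))
  if (!all(c(item, value) %in% names(data))) {
    abort(paste0("score_spwss: columns '", item, "' and '", value,
                 "' must be present"), class = "lagmed_input_error")
  }
  known <- unlist(spwss_items, use.names = FALSE)
  bad <- setdiff(unique(data[[item]]), known)
  if (length(bad) > 0) {
    abort(paste0("score_spwss: unknown SPWSS item label(s): ",
                 paste(bad, collapse = ", ")),
          class = "lagmed_input_error")
  }
  v <- data[[value]]
  if (any(!is.na(v) & (v < 0 | v > 8))) {
    abort("score_spwss: SPWSS item responses must lie in [0, 8]",
          class = "lagmed_input_error")
  }

  id_cols <- setdiff(names(data), c(item, value))
  data |>
    dplyr::rename(.item = dplyr::all_of(item), .value = dplyr::all_of(value)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(id_cols))) |>
    dplyr::summarise(
      social_anxiety = prorated_score(
        .data$.value[.data$.item %in% spwss_items$anxiety], 4, "total"),
      sfa = prorated_score(
        .data$.value[.data$.item %in% spwss_items$sfa], 2, "mean"),
      n_items_social = sum(!is.na(.data$.value[.data$.item %in% spwss_items$anxiety])),
      n_items_sfa = sum(!is.na(.data$.value[.data$.item %in% spwss_items$sfa])),
      .groups = "drop"
    )
}

#' Standardization parameters for the SCQ composite
#'
#' The Social Cognitions Questionnaire yields a frequency mean (1-5) and a
#' belief mean (0-100); both are z-scored against sample moments and
#' averaged into a single composite. `scq_params()` builds the moment
#' container directly; `estimate_scq_params()` computes it from scored data,
#' by default pooling all occasions of all participants in a sample (the
#' composite then stays comparable across the course of treatment), with a
#' baseline-only window available as an alternative.
#'
#' @param freq_mean,freq_sd,belief_mean,belief_sd Moments used for
#'   standardization; spreads must be strictly positive.
#' @param provenance Label recording which sample/occasions the moments came
#'   from.
#' @return A list of class `scq_params`.
#' @export
scq_params <- function(freq_mean, freq_sd, belief_mean, belief_sd,
                       provenance = "user") {
  if (freq_sd <= 0 || belief_sd <= 0) {
    abort("scq_params: spreads must be strictly positive",
          class = "lagmed_input_error")
  }
  structure(
    list(freq_mean = freq_mean, freq_sd = freq_sd,
         belief_mean = belief_mean, belief_sd = belief_sd,
         provenance = provenance),
    class = "scq_params")
}

#' @rdname scq_params
#' @param data Data frame with per-occasion subscale means.
#' @param freq,belief Column names of the frequency and belief subscale means.
#' @param window `"all"` (default) uses every occasion; `"baseline"` uses
#'   only rows where `baseline_flag` is `TRUE`.
#' @param baseline_flag Column name of a logical baseline indicator (only
#'   needed for `window = "baseline"`).
#' @export
estimate_scq_params <- function(data, freq = "scq_freq", belief = "scq_belief",
                                window = c("all", "baseline"),
                                baseline_flag = "is_baseline") {
  window <- match.arg(window)
  stopifnot(is.data.frame(data), all(c(freq, belief) %in% names(data)))
  if (window == "baseline") {
    stopifnot(baseline_flag %in% names(data))
    data <- dplyr::filter(data, .data[[baseline_flag]])
  }
  scq_params(
    freq_mean = mean(data[[freq]], na.rm = TRUE),
    freq_sd = sd(data[[freq]], na.rm = TRUE),
    belief_mean = mean(data[[belief]], na.rm = TRUE),
    belief_sd = sd(data[[belief]], na.rm = TRUE),
    provenance = paste0(window, "-occasions, n_rows=", nrow(data))
  )
}

#' SCQ composite z score
#'
#' Standardises the frequency and belief subscale means against the supplied
#' moments and averages the two z scores:
#' `((freq - mu_f)/s_f + (belief - mu_b)/s_b) / 2`.
#'
#' @param freq_mean Numeric vector of frequency subscale means, in \[1, 5\].
#' @param belief_mean Numeric vector of belief subscale means, in \[0, 100\].
#' @param params An [scq_params] object.
#' @return Numeric vector of composite z scores.
#' @export
scq_composite <- function(freq_mean, belief_mean, params) {
  stopifnot(inherits(params, "scq_params"))
  if (any(!is.na(freq_mean) & (freq_mean < 1 | freq_mean > 5))) {
    abort("scq_composite: frequency means must lie in [1, 5]",
          class = "lagmed_input_error")
  }
  if (any(!is.na(belief_mean) & (belief_mean < 0 | belief_mean > 100))) {
    abort("scq_composite: belief means must lie in [0, 100]",
          class = "lagmed_input_error")
  }
  ((freq_mean - params$freq_mean) / params$freq_sd +
     (belief_mean - params$belief_mean) / params$belief_sd) / 2
}

#' Cronbach's alpha
#'
#' Coefficient alpha, `k/(k-1) * (1 - sum(item variances) / var(total))`,
#' computed listwise on complete rows.
#'
#' @param items Matrix or data frame, one column per item, one row per
#'   assessment occasion.
#' @return A single number; `NA` (with attribute `flag =
#'   "zero_total_variance"`) when the total score does not vary.
#' @export
cronbach_alpha <- function(items) {
  x <- as.matrix(items)
  storage.mode(x) <- "double"
  if (ncol(x) < 2) {
    abort("cronbach_alpha: need at least 2 items", class = "lagmed_input_error")
  }
  x <- x[complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3) {
    abort("cronbach_alpha: need at least 3 complete occasions",
          class = "lagmed_input_error")
  }
  k <- ncol(x)
  total_var <- var(rowSums(x))
  if (total_var <= .Machine$double.eps) {
    return(structure(NA_real_, flag = "zero_total_variance"))
  }
  k / (k - 1) * (1 - sum(apply(x, 2, var)) / total_var)
}

#' Pre-post Cohen's d (pooled-SD form)
#'
#' `d = (pre_mean - post_mean) / sqrt((pre_sd^2 + post_sd^2) / 2)`; positive
#' when scores decrease over treatment.
#'
#' @param pre_mean,pre_sd,post_mean,post_sd Numeric vectors; SDs must be
#'   strictly positive.
#' @return Numeric vector of standardized mean changes.
#' @examples
#' cohen_d_pooled(21.07, 5.04, 9.41, 7.18)  # ~1.88
#' @export
cohen_d_pooled <- function(pre_mean, pre_sd, post_mean, post_sd) {
  if (any(pre_sd <= 0 | post_sd <= 0, na.rm = TRUE)) {
    abort("cohen_d_pooled: standard deviations must be strictly positive",
          class = "lagmed_input_error")
  }
  (pre_mean - post_mean) / sqrt((pre_sd^2 + post_sd^2) / 2)
}

#' Apply session and questionnaire inclusion criteria
#'
#' Participants must have attended a minimum number of sessions and completed
#' the weekly questionnaires on a minimum number of occasions. The session
#' criterion is checked first, so a participant failing both is tallied under
#' the session criterion (sequential accounting).
#'
#' @param data Scored long-format data frame, one row per attended session,
#'   with a `participant_id` column and one or more score columns. A row
#'   counts as a completed questionnaire occasion when at least one of
#'   `score_cols` is non-missing.
#' @param min_sessions,min_questionnaires Inclusion thresholds (default 5
#'   and 5).
#' @param score_cols Character vector of score columns; defaults to all
#'   numeric columns other than `participant_id`, `session_index`,
#'   `days_since_first_session`.
#' @return A list with `included` (filtered tibble) and `tally`
#'   (tibble of `reason`, `n_excluded`).
#' @export
apply_inclusion_criteria <- function(data, min_sessions = 5,
                                     min_questionnaires = 5,
                                     score_cols = NULL) {
  stopifnot(min_sessions >= 1, min_questionnaires >= 1)
  if (nrow(data) == 0) {
    return(list(
      included = tibble::as_tibble(data),
      tally = tibble::tibble(
        reason = c("too_few_sessions", "too_few_questionnaires"),
        n_excluded = c(0L, 0L))))
  }
  if (is.null(score_cols)) {
    score_cols <- setdiff(
      names(data)[vapply(data, is.numeric, logical(1))],
      c("participant_id", "session_index", "days_since_first_session"))
  }
  per <- data |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_sessions = dplyr::n(),
      n_questionnaires = sum(rowSums(!is.na(
        dplyr::pick(dplyr::all_of(score_cols)))) > 0),
      .groups = "drop") |>
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$n_sessions < .env$min_sessions ~ "too_few_sessions",
        .data$n_questionnaires < .env$min_questionnaires ~ "too_few_questionnaires",
        TRUE ~ "included"))
  tally <- tibble::tibble(
    reason = c("too_few_sessions", "too_few_questionnaires"),
    n_excluded = c(sum(per$reason == "too_few_sessions"),
                   sum(per$reason == "too_few_questionnaires")))
  keep <- per$participant_id[per$reason == "included"]
  list(
    included = tibble::as_tibble(data[data$participant_id %in% keep, ]),
    tally = tally)
}
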