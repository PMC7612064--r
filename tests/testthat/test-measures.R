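make_spwss_long <- function(anxiety, sfa, id = 1, session = 1) {
  tibble::tibble(
    participant_id = id, session_index = session,
    item = c(spwss_items$anxiety, spwss_items$sfa),
    value = c(anxiety, sfa))
}

test_that("SPWSS scoring sums anxiety items and averages attention items", {
  cases <- list(
    list(anx = c(0, 0, 0, 0), sfa = c(0, 0), total = 0, sfa_mean = 0),
    list(anx = c(8, 8, 8, 8), sfa = c(8, 8), total = 32, sfa_mean = 8),
    list(anx = c(6, 5, 5, 5), sfa = c(5, 6), total = 21, sfa_mean = 5.5))
  for (cs in cases) {
    out <- score_spwss(make_spwss_long(cs$anx, cs$sfa))
    expect_equal(out$social_anxiety, cs$total)
    expect_equal(out$sfa, cs$sfa_mean)
  }
})

test_that("SPWSS proration requires 75% of items and never errors on all-missing", {
  # 3 of 4 anxiety items: prorated mean * 4
  out <- score_spwss(make_spwss_long(c(4, 6, 8, NA), c(5, NA)))
  expect_equal(out$social_anxiety, 6 * 4)
  expect_true(is.na(out$sfa))  # 1 of 2 is below 75%
  # all four anxiety items missing -> missing score, not an error
  out2 <- score_spwss(make_spwss_long(rep(NA_real_, 4), c(3, 4)))
  expect_true(is.na(out2$social_anxiety))
  expect_equal(out2$sfa, 3.5)
})

test_that("SPWSS scoring rejects unknown labels and out-of-range values", {
  bad <- make_spwss_long(c(1, 2, 3, 4), c(5, 6))
  bad$item[1] <- "self_esteem"
  expect_error(score_spwss(bad), class = "lagmed_input_error")
  bad2 <- make_spwss_long(c(9, 2, 3, 4), c(5, 6))
  expect_error(score_spwss(bad2), class = "lagmed_input_error")
})

test_that("SCQ composite is the average of the two z scores", {
  p <- scq_params(freq_mean = 2.5, freq_sd = 0.8,
                  belief_mean = 55, belief_sd = 20)
  expect_equal(scq_composite(2.5, 55, p), 0)
  expect_equal(scq_composite(2.5 + 0.8, 75, p), 1)
  expect_equal(scq_composite(2.5 + 1.6, 55, p), 1)
  expect_error(scq_composite(0.5, 55, p), class = "lagmed_input_error")
  expect_error(scq_composite(2.5, 101, p), class = "lagmed_input_error")
  expect_error(scq_params(2.5, 0, 55, 20), class = "lagmed_input_error")
})

test_that("SCQ standardization windows pool the requested occasions", {
  d <- tibble::tibble(
    scq_freq = c(2, 3, 4, 1), scq_belief = c(40, 60, 80, 20),
    is_baseline = c(TRUE, FALSE, FALSE, TRUE))
  p_all <- estimate_scq_params(d)
  expect_equal(p_all$freq_mean, 2.5)
  p_base <- estimate_scq_params(d, window = "baseline")
  expect_equal(p_base$freq_mean, 1.5)
  expect_equal(p_base$belief_mean, 30)
})

test_that("Cronbach's alpha matches the covariance-matrix oracle", {
  # parallel duplicated items
  x <- cbind(a = c(1, 4, 2, 5), b = c(1, 4, 2, 5))
  expect_equal(cronbach_alpha(x), 1)
  # hand table, 3 items x 4 occasions
  h <- cbind(i1 = c(2, 4, 5, 7), i2 = c(3, 4, 6, 6), i3 = c(1, 3, 5, 8))
  expect_equal(cronbach_alpha(h), alpha_covmat_oracle(h), tolerance = 1e-12)
  # independent noise -> alpha near zero
  z <- withr::with_seed(5, matrix(rnorm(1000), 500, 2))
  expect_lt(abs(cronbach_alpha(z)), 0.15)
  # property: agreement with the oracle on random complete matrices
  for (s in 1:5) {
    m <- withr::with_seed(s, matrix(rnorm(60, sd = s), 12, 5))
    expect_equal(cronbach_alpha(m), alpha_covmat_oracle(m), tolerance = 1e-12)
  }
})

test_that("Cronbach's alpha flags degenerate input and enforces minimums", {
  const <- cbind(c(3, 3, 3, 3), c(5, 5, 5, 5))
  expect_true(is.na(cronbach_alpha(const)))
  expect_identical(attr(cronbach_alpha(const), "flag"), "zero_total_variance")
  expect_error(cronbach_alpha(matrix(1:6, ncol = 1)),
               class = "lagmed_input_error")
  expect_error(cronbach_alpha(matrix(rnorm(4), 2, 2)),
               class = "lagmed_input_error")
})

test_that("pooled Cohen's d has the expected symmetries", {
  expect_equal(cohen_d_pooled(10, 2, 10, 3), 0)
  d1 <- cohen_d_pooled(21, 5, 9, 7)
  expect_equal(cohen_d_pooled(9, 5, 21, 7), -d1)        # antisymmetry
  expect_equal(cohen_d_pooled(42, 10, 18, 14), d1)      # scale invariance
  expect_error(cohen_d_pooled(10, 0, 9, 1), class = "lagmed_input_error")
})

test_that("inclusion criteria use sequential accounting", {
  mk <- function(id, n_sessions, n_answered) {
    tibble::tibble(
      participant_id = id, session_index = seq_len(n_sessions),
      days_since_first_session = (seq_len(n_sessions) - 1) * 7,
      sfa = c(rep(1, n_answered), rep(NA_real_, n_sessions - n_answered)))
  }
  cohort <- dplyr::bind_rows(
    purrr::map(1:10, ~ mk(.x, 12, 10)),   # eligible
    mk(11, 4, 4),                         # fails sessions (and questionnaires)
    mk(12, 12, 3))                        # fails questionnaires only
  res <- apply_inclusion_criteria(cohort, 5, 5)
  expect_setequal(unique(res$included$participant_id), 1:10)
  tl <- tibble::deframe(res$tally)
  expect_equal(tl[["too_few_sessions"]], 1)
  expect_equal(tl[["too_few_questionnaires"]], 1)
})

test_that("inclusion criteria handle an empty cohort", {
  empty <- tibble::tibble(participant_id = integer(), session_index = integer(),
                          days_since_first_session = numeric(), sfa = numeric())
  res <- apply_inclusion_criteria(empty)
  expect_equal(nrow(res$included), 0)
  expect_equal(sum(res$tally$n_excluded), 0)
})
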