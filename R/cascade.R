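#' Configuration for care-continuum classification
#'
#' @param suppression_threshold copies/mL; a participant is suppressed when
#'   the relevant viral load is strictly below this (default 200)
#' @param window_tolerance_days the "+/- 1 month" reporting tolerance in days
#'   (default 30)
#' @param retention_gap_days minimum days between two tests for retention
#'   (default 90)
#' @param followup_months months after enrollment of the two follow-up
#'   reporting timepoints (default `c(6, 12)`)
#' @param missing_rule `"missing_as_false"` counts participants with no test
#'   in a window as not achieving the outcome (denominator = all enrolled);
#'   `"complete_case"` drops them from the denominator in [cascade_table()]
#' @return list of class `cascade_config`
#' @export
cascade_config <- function(suppression_threshold = 200,
                           window_tolerance_days = 30L,
                           retention_gap_days = 90L,
                           followup_months = c(6L, 12L),
                           missing_rule = c("missing_as_false", "complete_case")) {
  missing_rule <- match.arg(missing_rule)
  if (suppression_threshold <= 0 || window_tolerance_days <= 0 || retention_gap_days <= 0)
    stop_data("cascade config values must be positive")
  structure(list(
    suppression_threshold = suppression_threshold,
    window_tolerance_days = as.integer(window_tolerance_days),
    retention_gap_days = as.integer(retention_gap_days),
    followup_months = as.integer(followup_months),
    missing_rule = missing_rule
  ), class = "cascade_config")
}

# test dates (days relative to anchor) falling in the engagement/retention
# window. The anchor-day test itself is a study procedure and never counts;
# forward windows are (0, horizon + tolerance], the baseline lookback is
# [-12 months, 0).
window_days <- function(tests, anchor_date, config, lookback, horizon_days) {
  d <- as.integer(tests$test_date - as.Date(anchor_date))
  if (lookback) d[d >= -months_to_days(12) & d < 0]
  else d[d > 0 & d <= horizon_days + config$window_tolerance_days]
}

#' Classify engagement in care
#'
#' Engagement at a timepoint is at least one viral-load test within the
#' reporting window: for follow-up timepoints, the `horizon_days` after the
#' anchor (enrollment) date plus the +/- 1-month tolerance; for baseline
#' (`lookback = TRUE`), the 12 months before enrollment. The anchor-day test
#' is excluded in both directions.
#'
#' @param tests one participant's lab tests (tibble with `test_date`)
#' @param anchor_date enrollment date
#' @param config a [cascade_config()]
#' @param lookback use the 12-months-prior baseline window
#' @param horizon_days forward window length before tolerance (default 360)
#' @return logical
#' @export
classify_engagement <- function(tests, anchor_date, config = cascade_config(),
                                lookback = FALSE, horizon_days = 360L) {
  length(window_days(tests, anchor_date, config, lookback, horizon_days)) >= 1
}

#' Classify retention in care
#'
#' Retention is at least two viral-load tests at least `retention_gap_days`
#' apart within the same window engagement uses.
#'
#' @inheritParams classify_engagement
#' @return logical
#' @export
classify_retention <- function(tests, anchor_date, config = cascade_config(),
                               lookback = FALSE, horizon_days = 360L) {
  d <- window_days(tests, anchor_date, config, lookback, horizon_days)
  length(d) >= 2 && (max(d) - min(d)) >= config$retention_gap_days
}

#' Classify viral suppression at a reporting date
#'
#' True iff the most recent test within +/- tolerance of the reporting date
#' has viral load strictly below the suppression threshold; false when no
#' test falls in that window. Ties on the same day resolve to the last test
#' recorded that day.
#'
#' @param tests one participant's lab tests (`test_date`, `viral_load`)
#' @param report_date the reporting timepoint date
#' @param config a [cascade_config()]
#' @return logical
#' @export
classify_suppression <- function(tests, report_date, config = cascade_config()) {
  d <- as.integer(tests$test_date - as.Date(report_date))
  in_win <- which(abs(d) <= config$window_tolerance_days)
  if (!length(in_win)) return(FALSE)
  latest <- in_win[order(d[in_win])][length(in_win)]
  tests$viral_load[latest] < config$suppression_threshold
}

#' Classify all care-continuum outcomes for a cohort
#'
#' For each participant: baseline (t0) engagement/retention over the 12
#' months before enrollment and suppression from the enrollment-day test;
#' 6-month (t1) and 12-month (t2) engagement/retention over the elapsed
#' post-enrollment window (6 respectively 12 months, + tolerance) and
#' suppression from the test nearest the reporting date.
#'
#' @param participants tibble with `id`, `enrollment_date`
#' @param lab_tests tibble with `participant_id`, `test_date`, `viral_load`
#' @param config a [cascade_config()]
#' @return tibble: participant_id, timepoint (t0/t1/t2), engaged, retained,
#'   suppressed, n_tests_in_window
#' @export
cascade_statuses <- function(participants, lab_tests, config = cascade_config()) {
  split_tests <- split(lab_tests[c("test_date", "viral_load")], lab_tests$participant_id)
  tp_names <- c("t0", "t1", "t2")
  horizons <- months_to_days(config$followup_months)
  out <- vector("list", nrow(participants))
  for (i in seq_len(nrow(participants))) {
    pid <- participants$id[i]
    enr <- participants$enrollment_date[i]
    tst <- split_tests[[pid]] %||% tibble::tibble(test_date = as.Date(character()), viral_load = integer())
    eng <- ret <- sup <- logical(3)
    ntw <- integer(3)
    # t0
    eng[1] <- classify_engagement(tst, enr, config, lookback = TRUE)
    ret[1] <- classify_retention(tst, enr, config, lookback = TRUE)
    sup[1] <- classify_suppression(tst, enr, config)
    ntw[1] <- length(window_days(tst, enr, config, TRUE, 0L))
    for (j in 1:2) {
      eng[j + 1] <- classify_engagement(tst, enr, config, horizon_days = horizons[j])
      ret[j + 1] <- classify_retention(tst, enr, config, horizon_days = horizons[j])
      sup[j + 1] <- classify_suppression(tst, enr + horizons[j], config)
      ntw[j + 1] <- length(window_days(tst, enr, config, FALSE, horizons[j]))
    }
    out[[i]] <- tibble::tibble(participant_id = pid, timepoint = tp_names,
                               engaged = eng, retained = ret, suppressed = sup,
                               n_tests_in_window = ntw)
  }
  dplyr::bind_rows(out)
}

#' Tabulate cohort-level care-continuum proportions
#'
#' Counts and proportions of engaged / retained / suppressed participants at
#' each timepoint. Under the default missing-as-false rule the denominator
#' is every enrolled participant; under complete-case it is participants
#' with at least one test in the timepoint's window.
#'
#' @param statuses tibble from [cascade_statuses()]
#' @param config a [cascade_config()]
#' @return tibble: timepoint, n, and count/proportion per outcome
#' @export
cascade_table <- function(statuses, config = cascade_config()) {
  if (nrow(statuses) == 0) stop_data("empty cohort: no statuses to tabulate")
  if (anyDuplicated(statuses[c("participant_id", "timepoint")]))
    stop_data("duplicate (participant, timepoint) status records")
  per_tp <- lapply(split(statuses, statuses$timepoint), function(df) {
    if (config$missing_rule == "complete_case") df <- df[df$n_tests_in_window > 0, ]
    n <- nrow(df)
    tibble::tibble(
      timepoint = df$timepoint[1], n = n,
      engaged = sum(df$engaged), engaged_prop = sum(df$engaged) / n,
      retained = sum(df$retained), retained_prop = sum(df$retained) / n,
      suppressed = sum(df$suppressed), suppressed_prop = sum(df$suppressed) / n
    )
  })
  dplyr::bind_rows(per_tp)
}
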