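#' Eligibility screening predicates
#'
#' Screening applies gating criteria (confirmed HIV diagnosis, local
#' residence with no plans to move, age 18+, able to take part in English,
#' not excluded for concurrent-study participation or institutionalization)
#' and then requires at least one criterion from Category A (out of care /
#' not suppressed) or Category B (newly diagnosed and not in care, or
#' at risk of falling out of care). All "N months" clauses use a 30-day
#' month.
#'
#' A screening record is a list with fields: `age_years`, `resident`,
#' `plans_to_move`, `english_ok`, `confirmed_hiv`, `missed_visits_6mo`,
#' `risk_factors` (character subset of [RISK_FACTORS], already limited to
#' the 12-month look-back for the behavioral-health and incarceration
#' items), `diagnosis_date`, `screening_date`, and optionally
#' `in_other_study` / `institutionalized` exclusions. `labs` is the
#' participant's viral-load history (tibble with `test_date`, `viral_load`),
#' sorted by date.
#'
#' @name screening
NULL

#' @rdname screening
#' @format NULL
#' @export
RISK_FACTORS <- c("unstable_housing", "unemployed_3mo",
                  "incarceration_history", "behavioral_health_12mo")

check_labs_sorted <- function(labs) {
  if (nrow(labs) > 1 && is.unsorted(labs$test_date))
    stop_data("lab history must be sorted by test date")
}

#' Category A criteria
#'
#' True when the participant (i) has had no viral-load test in the 8 months
#' (240 days) before screening, or (ii) has two consecutive detectable
#' (>= 200 copies/mL) viral-load results at least 90 days apart
#' ("consecutive" = adjacent in date order, no intervening test), or
#' (iii) missed 2 or more clinic visits in the last six months.
#'
#' @param record screening record (see [screening])
#' @param labs viral-load history sorted by date
#' @return list with `qualifies` (logical) and `reasons` (rule codes)
#' @export
screen_category_a <- function(record, labs) {
  check_labs_sorted(labs)
  reasons <- character()
  recent <- labs$test_date > record$screening_date - months_to_days(8) &
    labs$test_date <= record$screening_date
  if (!any(recent)) reasons <- c(reasons, "NO_VL_8MO")
  if (nrow(labs) >= 2) {
    pre <- labs[labs$test_date <= record$screening_date, ]
    if (nrow(pre) >= 2) {
      i <- seq_len(nrow(pre) - 1)
      hit <- pre$viral_load[i] >= 200 & pre$viral_load[i + 1] >= 200 &
        as.integer(pre$test_date[i + 1] - pre$test_date[i]) >= 90
      if (any(hit)) reasons <- c(reasons, "TWO_DETECTABLE_90D")
    }
  }
  if (record$missed_visits_6mo >= 2) reasons <- c(reasons, "MISSED_2_VISITS")
  list(qualifies = length(reasons) > 0, reasons = reasons)
}

#' Category B criteria
#'
#' True when the participant (i) was newly diagnosed — diagnosis between 3
#' and 12 months before screening — and has had no viral-load test since
#' diagnosis, or (ii) self-reports at least one risk factor for falling out
#' of care (unstable housing, unemployment for 3+ months, incarceration
#' history, or a behavioral-health condition, the last two limited to the 12
#' months before enrollment).
#'
#' @inheritParams screen_category_a
#' @return list with `qualifies` and `reasons`
#' @export
screen_category_b <- function(record, labs) {
  check_labs_sorted(labs)
  if (!is.null(record$diagnosis_date) && !is.na(record$diagnosis_date) &&
      record$diagnosis_date > record$screening_date)
    stop_data("diagnosis_date after screening_date")
  reasons <- character()
  dx_known <- !is.null(record$diagnosis_date) && !is.na(record$diagnosis_date)
  if (dx_known) {
    dx_days <- as.integer(record$screening_date - record$diagnosis_date)
    newly_dx <- dx_days > months_to_days(3) && dx_days <= months_to_days(12)
    since_dx <- any(labs$test_date >= record$diagnosis_date &
                    labs$test_date <= record$screening_date)
    if (newly_dx && !since_dx) reasons <- c(reasons, "NEW_DX_NOT_IN_CARE")
  }
  rf <- intersect(record$risk_factors %||% character(), RISK_FACTORS)
  if (length(rf) > 0) reasons <- c(reasons, "RISK_FACTOR")
  list(qualifies = length(reasons) > 0, reasons = reasons)
}

#' Full eligibility determination
#'
#' Applies the gating criteria and exclusions, then Category A with
#' precedence over Category B (Category A is the study's primary stratum).
#'
#' @inheritParams screen_category_a
#' @return list with `eligible`, `category` (`"A"`, `"B"` or `"none"`) and
#'   `reasons`
#' @export
check_eligibility <- function(record, labs) {
  gate <- isTRUE(record$confirmed_hiv) && isTRUE(record$resident) &&
    !isTRUE(record$plans_to_move) && record$age_years >= 18 &&
    isTRUE(record$english_ok) && !isTRUE(record$in_other_study) &&
    !isTRUE(record$institutionalized)
  if (!gate) return(list(eligible = FALSE, category = "none", reasons = character()))
  a <- screen_category_a(record, labs)
  if (a$qualifies) return(list(eligible = TRUE, category = "A", reasons = a$reasons))
  b <- screen_category_b(record, labs)
  if (b$qualifies) return(list(eligible = TRUE, category = "B", reasons = b$reasons))
  list(eligible = FALSE, category = "none", reasons = character())
}

#' Screen a whole cohort
#'
#' Runs [check_eligibility()] over a participants table plus lab-test
#' streams and returns a screening report.
#'
#' @param participants tibble with the screening fields (see [screening])
#'   and an `id` column; `screening_date` defaults to `enrollment_date`
#' @param lab_tests tibble with `participant_id`, `test_date`, `viral_load`
#' @return tibble: id, eligible, category, reasons (semicolon-separated)
#' @export
screen_cohort <- function(participants, lab_tests) {
  split_tests <- split(lab_tests[c("test_date", "viral_load")], lab_tests$participant_id)
  empty <- tibble::tibble(test_date = as.Date(character()), viral_load = integer())
  rows <- lapply(seq_len(nrow(participants)), function(i) {
    p <- as.list(participants[i, ])
    p$screening_date <- p$screening_date %||% p$enrollment_date
    p$risk_factors <- RISK_FACTORS[c(isTRUE(p$unstable_housing), isTRUE(p$unemployed_3mo),
                                     isTRUE(p$incarceration_history), isTRUE(p$behavioral_health_12mo))]
    labs <- split_tests[[p$id]] %||% empty
    labs <- labs[labs$test_date < p$screening_date, , drop = FALSE]
    res <- check_eligibility(p, labs)
    tibble::tibble(id = p$id, eligible = res$eligible, category = res$category,
                   reasons = paste(res$reasons, collapse = ";"))
  })
  dplyr::bind_rows(rows)
}
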