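#' Conditional financial incentive schedule
#'
#' The intervention schedule: USD10 per completed lab visit (capped at 4 per
#' participant-year), USD50 for viral suppression at each of the 6- and
#' 12-month reporting timepoints, for an intervention cap of USD140. Survey
#' compensation (USD50 baseline, USD15 follow-up) is tracked but sits outside
#' the intervention cap. All amounts are held in integer cents so ledger
#' identities are exact.
#'
#' @param lab_amount USD per lab-visit incentive
#' @param lab_max_count maximum lab incentives per participant
#' @param suppression_amount USD per suppression incentive
#' @param survey_baseline,survey_followup USD survey compensation
#' @return list of class `incentive_schedule` with amounts in cents
#' @export
incentive_schedule <- function(lab_amount = 10, lab_max_count = 4L,
                               suppression_amount = 50,
                               survey_baseline = 50, survey_followup = 15) {
  s <- list(
    lab_cents = as.integer(round(lab_amount * 100)),
    lab_max_count = as.integer(lab_max_count),
    suppression_cents = as.integer(round(suppression_amount * 100)),
    survey_baseline_cents = as.integer(round(survey_baseline * 100)),
    survey_followup_cents = as.integer(round(survey_followup * 100))
  )
  s$intervention_cap_cents <- s$lab_cents * s$lab_max_count + 2L * s$suppression_cents
  structure(s, class = "incentive_schedule")
}

INCENTIVE_EVENT_TYPES <- c("LAB", "SUPPRESSION_6M", "SUPPRESSION_12M",
                           "SURVEY_BASELINE", "SURVEY_FOLLOWUP")
INTERVENTION_EVENT_TYPES <- c("LAB", "SUPPRESSION_6M", "SUPPRESSION_12M")

empty_ledger <- function() {
  tibble::tibble(participant_id = character(), event_type = character(),
                 date = as.Date(character()), amount_cents = integer(),
                 distributed = logical())
}

#' Accrue one incentive event against a participant's ledger
#'
#' Applies the schedule's conditioning rules: lab incentives only while the
#' participant's prior lab count is below the cap, each suppression incentive
#' at most once, and the per-participant intervention total can never exceed
#' the cap. Returns the event to append, or `NULL` with an audit code when
#' the trigger earns nothing.
#'
#' @param ledger this participant's prior events (tibble as from
#'   [empty_ledger()]), sorted by date
#' @param trigger one of `"lab_completed"`, `"suppressed_6m"`,
#'   `"suppressed_12m"`, `"survey_baseline"`, `"survey_followup"`
#' @param participant_id id for the new event
#' @param date event date
#' @param schedule an [incentive_schedule()]
#' @param distributed whether the incentive was physically handed over; events
#'   earned but pending at study close are still counted as distributed for
#'   analysis, the flag preserves the operational distinction
#' @return list with `event` (one-row tibble or NULL) and `audit` code
#' @export
accrue <- function(ledger, trigger, participant_id, date,
                   schedule = incentive_schedule(), distributed = TRUE) {
  if (is.unsorted(ledger$date)) stop_data("ledger must be sorted by date")
  mk <- function(type, cents) {
    tibble::tibble(participant_id = participant_id, event_type = type,
                   date = as.Date(date), amount_cents = as.integer(cents),
                   distributed = distributed)
  }
  intervention_total <- sum(ledger$amount_cents[ledger$event_type %in% INTERVENTION_EVENT_TYPES])
  res <- switch(trigger,
    lab_completed = {
      n_lab <- sum(ledger$event_type == "LAB")
      if (n_lab >= schedule$lab_max_count) {
        list(event = NULL, audit = "LAB_CAP_REACHED")
      } else list(event = mk("LAB", schedule$lab_cents), audit = "OK")
    },
    suppressed_6m = {
      if (any(ledger$event_type == "SUPPRESSION_6M")) {
        list(event = NULL, audit = "DUPLICATE_SUPPRESSION")
      } else list(event = mk("SUPPRESSION_6M", schedule$suppression_cents), audit = "OK")
    },
    suppressed_12m = {
      if (any(ledger$event_type == "SUPPRESSION_12M")) {
        list(event = NULL, audit = "DUPLICATE_SUPPRESSION")
      } else list(event = mk("SUPPRESSION_12M", schedule$suppression_cents), audit = "OK")
    },
    survey_baseline = list(event = mk("SURVEY_BASELINE", schedule$survey_baseline_cents), audit = "OK"),
    survey_followup = list(event = mk("SURVEY_FOLLOWUP", schedule$survey_followup_cents), audit = "OK"),
    stop_data("unknown incentive trigger '%s'", trigger)
  )
  if (!is.null(res$event) && res$event$event_type %in% INTERVENTION_EVENT_TYPES &&
      intervention_total + res$event$amount_cents > schedule$intervention_cap_cents) {
    return(list(event = NULL, audit = "INTERVENTION_CAP_EXCEEDED"))
  }
  res
}

#' Build the full incentive ledger from cascade output and lab tests
#'
#' Lab incentives accrue on post-enrollment lab visits (the enrollment-day
#' baseline test is study compensation, not a conditional incentive), capped
#' per the schedule; suppression incentives accrue from the 6- and 12-month
#' cascade suppression classifications; survey compensation accrues at
#' baseline for everyone and at follow-up for participants seen in the
#' 12-month window.
#'
#' @param participants participants tibble (needs `id`, `enrollment_date`)
#' @param lab_tests lab tests tibble (`participant_id`, `test_date`)
#' @param statuses cascade statuses tibble as from [cascade_statuses()]
#' @param schedule an [incentive_schedule()]
#' @return ledger tibble with one row per accrued event
#' @export
build_ledger <- function(participants, lab_tests, statuses,
                         schedule = incentive_schedule()) {
  rows <- vector("list", nrow(participants))
  for (i in seq_len(nrow(participants))) {
    pid <- participants$id[i]
    enr <- participants$enrollment_date[i]
    led <- empty_ledger()
    push <- function(trigger, date) {
      r <- accrue(led, trigger, pid, date, schedule)
      if (!is.null(r$event)) led <<- dplyr::bind_rows(led, r$event)
    }
    post <- sort(lab_tests$test_date[lab_tests$participant_id == pid &
                                     lab_tests$test_date > enr])
    st <- statuses[statuses$participant_id == pid, ]
    triggers <- data.frame(trigger = "survey_baseline", date = enr)
    if (length(post))
      triggers <- rbind(triggers, data.frame(trigger = "lab_completed", date = post))
    if (any(st$timepoint == "t1" & st$suppressed))
      triggers <- rbind(triggers, data.frame(trigger = "suppressed_6m", date = enr + 180))
    if (any(st$timepoint == "t2" & st$suppressed))
      triggers <- rbind(triggers, data.frame(trigger = "suppressed_12m", date = enr + 360))
    if (any(st$timepoint == "t2" & st$n_tests_in_window > 0))
      triggers <- rbind(triggers, data.frame(trigger = "survey_followup", date = enr + 360))
    triggers <- triggers[order(triggers$date), , drop = FALSE]
    for (j in seq_len(nrow(triggers))) push(triggers$trigger[j], triggers$date[j])
    rows[[i]] <- led
  }
  dplyr::bind_rows(rows)
}

#' Summarise an incentive ledger
#'
#' Reports, for lab incentives, how many participants received at least k
#' incentives for k = 1..cap, the total number of lab incentives distributed
#' (which equals the sum of the at-least-k counts: a participant with m lab
#' events contributes to each of the first m), suppression incentive counts
#' per timepoint, and dollar totals by event type.
#'
#' @param ledger ledger tibble
#' @param schedule an [incentive_schedule()]
#' @return list with `at_least_k`, `total_lab_incentives`,
#'   `suppression_6m`, `suppression_12m`, `total_usd_by_type`
#' @export
ledger_summary <- function(ledger, schedule = incentive_schedule()) {
  kmax <- schedule$lab_max_count
  lab <- ledger[ledger$event_type == "LAB", ]
  per_pt <- table(factor(lab$participant_id))
  at_least_k <- vapply(seq_len(kmax), function(k) sum(per_pt >= k), integer(1))
  names(at_least_k) <- paste0("at_least_", seq_len(kmax))
  totals <- tapply(ledger$amount_cents, factor(ledger$event_type, INCENTIVE_EVENT_TYPES),
                   sum, default = 0L)
  list(
    at_least_k = at_least_k,
    total_lab_incentives = sum(at_least_k),
    suppression_6m = sum(ledger$event_type == "SUPPRESSION_6M"),
    suppression_12m = sum(ledger$event_type == "SUPPRESSION_12M"),
    total_usd_by_type = as.numeric(totals) / 100
  )
}
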