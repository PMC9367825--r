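#' Run configuration for the end-to-end pipeline
#'
#' @param out_dir output directory (created if needed)
#' @param seed master seed (drives simulation and cost-input generation)
#' @param cohort a [cohort_config()]; its seed is overridden by `seed`
#' @param cascade a [cascade_config()]
#' @param schedule an [incentive_schedule()]
#' @param constants an [econ_constants()]
#' @param participants_path,lab_tests_path,cost_inputs_path optional CSVs to
#'   load instead of simulating
#' @param random_effects fit the random-intercept trend variant as well
#' @return list of class `run_config`
#' @export
run_config <- function(out_dir, seed = 1L,
                       cohort = cohort_config(),
                       cascade = cascade_config(),
                       schedule = incentive_schedule(),
                       constants = econ_constants(),
                       participants_path = NULL, lab_tests_path = NULL,
                       cost_inputs_path = NULL, random_effects = FALSE) {
  for (p in c(participants_path, lab_tests_path, cost_inputs_path)) {
    if (!is.null(p) && !file.exists(p)) stop_data("input path does not exist: %s", p)
  }
  cohort$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), cohort = cohort,
                 cascade = cascade, schedule = schedule, constants = constants,
                 participants_path = participants_path, lab_tests_path = lab_tests_path,
                 cost_inputs_path = cost_inputs_path, random_effects = random_effects),
            class = "run_config")
}

#' Run the full evaluation pipeline
#'
#' simulate (or load) -> screen -> cascade -> incentives -> survey scores ->
#' trend + correlates models -> cost-utility analysis -> report. Every stage
#' writes its CSV/JSON artifact under `config$out_dir`; the returned report
#' lists per-stage record counts, warnings and an output manifest with row
#' counts and MD5 checksums. A fixed seed gives a bit-reproducible run.
#'
#' @param config a [run_config()]
#' @return list of class `run_report`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  counts <- list(); warnings_log <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_data("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # --- simulate / load -------------------------------------------------
  if (is.null(config$participants_path)) {
    sim <- stage("simulate", generate_cohort(config$cohort))
    participants <- sim$participants
    lab_tests <- sim$lab_tests
  } else {
    participants <- stage("load", read_participants(config$participants_path))
    lab_tests <- stage("load", read_lab_tests(config$lab_tests_path))
  }
  counts$participants <- nrow(participants)
  counts$lab_tests <- nrow(lab_tests)
  write_table(participants, out("participants.csv"))
  write_table(lab_tests, out("lab_tests.csv"))

  # --- screening -------------------------------------------------------
  screening <- stage("screen", screen_cohort(participants, lab_tests))
  counts$eligible <- sum(screening$eligible)
  write_table(screening, out("screening.csv"))

  # --- cascade ---------------------------------------------------------
  statuses <- stage("cascade", cascade_statuses(participants, lab_tests, config$cascade))
  tab <- cascade_table(statuses, config$cascade)
  write_table(statuses, out("cascade.csv"))
  write_table(tab, out("cascade_table.csv"))
  counts$cascade_rows <- nrow(statuses)

  # --- incentives ------------------------------------------------------
  ledger <- stage("incentives", build_ledger(participants, lab_tests, statuses, config$schedule))
  led_out <- ledger
  led_out$amount_usd <- led_out$amount_cents / 100
  write_table(led_out[c("participant_id", "event_type", "date", "amount_usd")],
              out("incentive_events.csv"), money_cols = "amount_usd")
  summ <- ledger_summary(ledger, config$schedule)
  counts$incentive_events <- nrow(ledger)

  # --- survey scores ---------------------------------------------------
  scores <- stage("surveys", score_surveys(participants))
  write_table(scores, out("scores.csv"))
  counts$scored <- nrow(scores)

  # --- models ----------------------------------------------------------
  long <- build_long_records(statuses)
  trends <- lapply(c("engagement", "retention", "suppression"), function(oc)
    stage("models", fit_time_trend(long, oc, random_effects = config$random_effects)))
  trend_df <- dplyr::bind_rows(lapply(trends, function(tf) tibble::tibble(
    outcome = tf$outcome, coef_time = tf$coef_time, se = tf$se, p_value = tf$p_value,
    prob_t0 = tf$predicted_probs[1], prob_t1 = tf$predicted_probs[2],
    prob_t2 = tf$predicted_probs[3], n_obs = tf$n_obs, model = tf$model)))
  write_table(trend_df, out("trend_fits.csv"))

  corr_data <- assemble_correlates_data(participants, statuses, scores)
  corr <- dplyr::bind_rows(lapply(c("engagement", "retention", "suppression"), function(oc) {
    fit <- stage("models", fit_benchmark_correlates(corr_data, oc))
    if (length(attr(fit, "dropped_levels")))
      warnings_log <<- c(warnings_log, paste0(oc, ": dropped separated level(s) ",
                                              paste(attr(fit, "dropped_levels"), collapse = ", ")))
    fit
  }))
  write_table(corr, out("correlates.csv"))

  # --- econ ------------------------------------------------------------
  if (!is.null(config$cost_inputs_path)) {
    ci <- stage("econ", read_cost_inputs(config$cost_inputs_path))
  } else {
    newly <- newly_suppressed_by_site(participants, statuses)
    contacts <- table(participants$site[match(lab_tests$participant_id, participants$id)])
    profiles <- tibble::tibble(
      clinic_id = newly$site,
      n_clients = as.integer(table(participants$site)[newly$site]),
      n_contacts = pmax(1L, as.integer(contacts[newly$site])),
      net_suppressed = newly$n
    )
    ci <- stage("econ", generate_cost_inputs(profiles, seed = config$seed + 1L))
  }
  ci_use <- ci[ci$net_suppressed > 0, , drop = FALSE]
  if (nrow(ci_use) < nrow(ci))
    warnings_log <- c(warnings_log, "econ: clinics with zero net suppression excluded from cost-utility ratios")
  econ <- stage("econ", cost_utility_analysis(ci_use, config$constants))
  write_table(econ, out("econ_table.csv"))
  jsonlite::write_json(list(cost_utility = econ, incentive_summary = summ),
                       out("econ_report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # --- manifest --------------------------------------------------------
  files <- sort(list.files(config$out_dir, pattern = "\\.(csv|json)$"))
  manifest <- tibble::tibble(
    file = files,
    rows = vapply(files, function(f) length(readLines(out(f), warn = FALSE)), integer(1)),
    md5 = unname(tools::md5sum(file.path(config$out_dir, files)))
  )
  write_table(manifest, out("manifest.csv"))
  structure(list(counts = counts, warnings = warnings_log, manifest = manifest,
                 incentive_summary = summ, trend_fits = trends, econ = econ),
            class = "run_report")
}

#' Net newly suppressed participants per site
#'
#' The cost-utility person-years proxy: participants suppressed at either
#' follow-up timepoint who were not suppressed at baseline, counted per
#' enrollment site.
#'
#' @param participants participants tibble (needs `id`, `site`)
#' @param statuses cascade statuses
#' @return tibble with `site` and `n`
#' @export
newly_suppressed_by_site <- function(participants, statuses) {
  s0 <- statuses[statuses$timepoint == "t0", c("participant_id", "suppressed")]
  fup <- statuses[statuses$timepoint != "t0", ]
  any_fup <- tapply(fup$suppressed, fup$participant_id, any)
  newly <- names(any_fup)[any_fup & !s0$suppressed[match(names(any_fup), s0$participant_id)]]
  site <- participants$site[match(newly, participants$id)]
  tb <- table(factor(site, levels = sort(unique(participants$site))))
  tibble::tibble(site = names(tb), n = as.integer(tb))
}
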