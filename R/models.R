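#' Build long-format records for the time-trend models
#'
#' One row per participant per timepoint per outcome, with time coded 0, 1,
#' 2 (baseline, 6-month, 12-month).
#'
#' @param statuses cascade statuses from [cascade_statuses()]
#' @return tibble: participant_id, time, engagement, retention, suppression
#' @export
build_long_records <- function(statuses) {
  tibble::tibble(
    participant_id = statuses$participant_id,
    time = c(t0 = 0, t1 = 1, t2 = 2)[statuses$timepoint],
    engagement = as.integer(statuses$engaged),
    retention = as.integer(statuses$retained),
    suppression = as.integer(statuses$suppressed)
  )
}

#' Fit the longitudinal time trend for one care-continuum outcome
#'
#' Pooled logistic regression of the binary outcome on time (a continuous
#' counter 0..2), with standard errors robust to within-participant
#' clustering (the default), or a random-intercept logistic model
#' (`random_effects = TRUE`). Predicted probabilities at t = 0, 1, 2 are the
#' model-implied probabilities (the margins-at-time analogue; with time the
#' only regressor the average marginal prediction equals the plug-in one).
#'
#' @param long_records tibble from [build_long_records()]
#' @param outcome `"engagement"`, `"retention"` or `"suppression"`
#' @param random_effects fit `lme4::glmer` with a participant random
#'   intercept instead of the pooled model
#' @return list of class `trend_fit`: outcome, coef_time, se, p_value,
#'   predicted_probs (t = 0, 1, 2), n_obs, model
#' @export
fit_time_trend <- function(long_records,
                           outcome = c("engagement", "retention", "suppression"),
                           random_effects = FALSE) {
  outcome <- match.arg(outcome)
  df <- data.frame(y = long_records[[outcome]], time = long_records$time,
                   id = long_records$participant_id)
  df <- df[stats::complete.cases(df), ]
  if (length(unique(df$time)) < 2) stop_data("time trend needs >= 2 distinct time values")
  if (!all(df$y %in% 0:1)) stop_data("outcome must be binary")
  if (random_effects) {
    fit <- lme4::glmer(y ~ time + (1 | id), data = df, family = stats::binomial())
    sm <- summary(fit)$coefficients
    b <- sm["time", "Estimate"]; se <- sm["time", "Std. Error"]
    fe <- lme4::fixef(fit)
    probs <- stats::plogis(fe[1] + fe[2] * 0:2)
  } else {
    fit <- stats::glm(y ~ time, data = df, family = stats::binomial())
    vc <- sandwich::vcovCL(fit, cluster = df$id)
    b <- stats::coef(fit)[["time"]]
    se <- sqrt(vc["time", "time"])
    probs <- stats::plogis(stats::coef(fit)[1] + b * 0:2)
  }
  p <- 2 * stats::pnorm(-abs(b / se))
  structure(list(outcome = outcome, coef_time = b, se = se, p_value = p,
                 predicted_probs = unname(probs), n_obs = nrow(df),
                 model = if (random_effects) "random_intercept" else "pooled_cluster_robust"),
            class = "trend_fit")
}

# benchmark covariates: baseline outcome + demographics + site + category,
# with the reference levels the correlates tables use
benchmark_terms <- function(outcome) {
  c(paste0("baseline_", outcome), "age_years", "race", "ethnicity", "gender",
    "relationship", "employment", "housing", "insurance", "site",
    "enrollment_category")
}

prep_correlates <- function(records) {
  df <- as.data.frame(records)
  relevel_if <- function(col, ref) {
    if (col %in% names(df) && !is.numeric(df[[col]]))
      df[[col]] <<- stats::relevel(factor(df[[col]]), ref = ref)
  }
  relevel_if("site", "A"); relevel_if("race", "white")
  relevel_if("gender", "female"); relevel_if("enrollment_category", "B")
  df
}

# covariates that are constant in the analysis subset carry no information
# and break the design matrix; they are removed with an audit note
drop_constant_terms <- function(df, terms) {
  keep <- vapply(terms, function(tm) {
    x <- df[[tm]]
    if (is.numeric(x)) stats::var(x) > 0 else nlevels(droplevels(factor(x))) >= 2
  }, logical(1))
  list(terms = terms[keep], dropped = terms[!keep])
}

# drop factor levels whose cell determines the outcome (complete
# separation), recording what was dropped — the analogue of a correlates
# table printing a dash for a site where no one achieved the outcome
drop_separated_levels <- function(df, yvar, terms) {
  dropped <- character()
  for (tm in terms) {
    if (!tm %in% names(df) || is.numeric(df[[tm]])) next
    for (lv in levels(df[[tm]])) {
      ys <- df[[yvar]][df[[tm]] == lv]
      # outcome constant within the cell => that level separates the fit;
      # only drop while at least two informative levels remain
      if (length(ys) > 0 && length(unique(ys)) == 1 &&
          stats::var(df[[yvar]]) > 0 && nlevels(droplevels(df[[tm]])) > 2) {
        df <- df[df[[tm]] != lv, , drop = FALSE]
        df[[tm]] <- droplevels(df[[tm]])
        dropped <- c(dropped, paste0(tm, ":", lv))
      }
    }
  }
  list(df = df, dropped = dropped)
}

glm_term_rows <- function(fit, n_obs, outcome, model) {
  sm <- summary(fit)$coefficients
  tibble::tibble(
    outcome = outcome,
    term = rownames(sm),
    coef = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    p_value = sm[, "Pr(>|z|)"],
    model = model,
    n_obs = n_obs
  )
}

#' Fit the benchmark baseline-correlates regression
#'
#' Single-level logistic regression of a 12-month care-continuum outcome on
#' the benchmark covariate set: the baseline value of the same outcome, age,
#' race/ethnicity, gender, relationship status, employment, housing,
#' insurance, enrollment site and enrollment category. Reference levels:
#' Site A, White, Female, Category B. Factor levels that perfectly determine
#' the outcome are dropped (recorded in the `dropped_levels` attribute).
#'
#' @param records one row per participant: the 12-month outcomes
#'   (`engagement`, `retention`, `suppression`), their `baseline_*`
#'   counterparts, and the benchmark covariates
#' @param outcome which outcome to model
#' @return tibble of term-level fits (class `correlate_fits`), attribute
#'   `dropped_levels`
#' @export
fit_benchmark_correlates <- function(records, outcome = c("engagement", "retention", "suppression")) {
  outcome <- match.arg(outcome)
  terms <- benchmark_terms(outcome)
  df <- prep_correlates(records)
  df <- df[stats::complete.cases(df[c(outcome, terms)]), ]
  sep <- drop_separated_levels(df, outcome, terms)
  ct <- drop_constant_terms(sep$df, terms)
  fml <- stats::reformulate(ct$terms, response = outcome)
  fit <- stats::glm(fml, data = sep$df, family = stats::binomial())
  out <- glm_term_rows(fit, nrow(sep$df), outcome, "benchmark")
  attr(out, "dropped_levels") <- sep$dropped
  attr(out, "dropped_terms") <- ct$dropped
  out
}

#' Fit an add-one-covariate correlates regression
#'
#' Adds a single additional baseline covariate to the benchmark model on the
#' complete-case subset for that covariate, and reports only the additional
#' term's row(s); `n_obs` reflects the complete-case subset.
#'
#' @inheritParams fit_benchmark_correlates
#' @param extra_covariate column name of the additional covariate
#' @return tibble with the extra term's coefficient rows only
#' @export
fit_add_one <- function(records, outcome = c("engagement", "retention", "suppression"),
                        extra_covariate) {
  outcome <- match.arg(outcome)
  if (!extra_covariate %in% names(records)) stop_data("unknown covariate '%s'", extra_covariate)
  if (all(is.na(records[[extra_covariate]]))) stop_data("covariate '%s' is entirely missing", extra_covariate)
  terms <- benchmark_terms(outcome)
  df <- prep_correlates(records)
  df <- df[stats::complete.cases(df[c(outcome, terms, extra_covariate)]), ]
  sep <- drop_separated_levels(df, outcome, terms)
  ct <- drop_constant_terms(sep$df, terms)
  fml <- stats::reformulate(c(ct$terms, extra_covariate), response = outcome)
  fit <- stats::glm(fml, data = sep$df, family = stats::binomial())
  if (any(is.na(stats::coef(fit)[grep(extra_covariate, names(stats::coef(fit)), fixed = TRUE)])))
    stop_data("covariate '%s' is collinear with the benchmark terms", extra_covariate)
  out <- glm_term_rows(fit, nrow(sep$df), outcome, "add_one")
  out <- out[startsWith(out$term, extra_covariate), ]
  attr(out, "dropped_levels") <- sep$dropped
  out
}

#' Assemble the correlates analysis frame
#'
#' Joins participant covariates, baseline and 12-month cascade outcomes, and
#' instrument scores into the one-row-per-participant frame the correlates
#' models consume.
#'
#' @param participants participants tibble
#' @param statuses cascade statuses
#' @param scores instrument scores from [score_surveys()]
#' @return tibble keyed by participant id
#' @export
assemble_correlates_data <- function(participants, statuses, scores) {
  t0 <- statuses[statuses$timepoint == "t0", ]
  t2 <- statuses[statuses$timepoint == "t2", ]
  base <- tibble::tibble(
    id = t0$participant_id,
    baseline_engagement = as.integer(t0$engaged),
    baseline_retention = as.integer(t0$retained),
    baseline_suppression = as.integer(t0$suppressed)
  )
  out12 <- tibble::tibble(
    id = t2$participant_id,
    engagement = as.integer(t2$engaged),
    retention = as.integer(t2$retained),
    suppression = as.integer(t2$suppressed)
  )
  df <- dplyr::left_join(participants, base, by = "id")
  df <- dplyr::left_join(df, out12, by = "id")
  # scores recompute some columns participants already carry (e.g. the raw
  # AUDIT-C score); keep the scored version
  dup <- setdiff(intersect(names(df), names(scores)), "participant_id")
  df <- df[setdiff(names(df), dup)]
  dplyr::left_join(df, scores, by = c(id = "participant_id"))
}
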