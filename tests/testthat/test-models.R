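make_long <- function(y_by_time, n_per_time) {
  tibble::tibble(
    participant_id = rep(sprintf("p%03d", seq_len(n_per_time)), 3),
    time = rep(0:2, each = n_per_time),
    engagement = unlist(lapply(1:3, function(j)
      as.integer(seq_len(n_per_time) <= y_by_time[j]))),
    retention = 0L, suppression = 0L
  )
}

test_that("a flat outcome yields a zero time coefficient and constant predicted probabilities", {
  long <- make_long(c(6, 6, 6), 10)    # 60% positive at every time
  fit <- fit_time_trend(long, "engagement")
  expect_lt(abs(fit$coef_time), 1e-8)
  expect_equal(fit$predicted_probs, rep(0.6, 3), tolerance = 1e-8)
  expect_equal(fit$n_obs, 30)
})

test_that("the pooled logit matches a direct likelihood maximiser to 1e-6", {
  # tiny worked case: 1/3, 2/3, 3/3 positive at t = 0, 1, 2
  long <- make_long(c(1, 2, 3), 3)
  fit <- fit_time_trend(long, "engagement")
  X <- cbind(1, long$time)
  beta <- oracle_logit_mle(long$engagement, X)
  expect_equal(fit$coef_time, beta[2], tolerance = 1e-6)

  # random small datasets, <= 50 rows
  set.seed(321)
  for (i in 1:20) {
    n <- sample(12:50, 1)
    x <- stats::rnorm(n)
    y <- stats::rbinom(n, 1, stats::plogis(-0.3 + 0.8 * x))
    if (length(unique(y)) < 2) next
    g <- stats::glm(y ~ x, family = stats::binomial())
    beta <- oracle_logit_mle(y, cbind(1, x))
    expect_equal(unname(stats::coef(g)), beta, tolerance = 1e-6)
  }
})

test_that("a generated rising engagement trend is detected with a positive, significant slope", {
  sim <- generate_cohort(cohort_config(n_participants = 781, seed = 29))
  st <- cascade_statuses(sim$participants, sim$lab_tests)
  long <- build_long_records(st)
  fit <- fit_time_trend(long, "engagement")
  expect_gt(fit$coef_time, 0)
  expect_lt(fit$p_value, 0.05)
  expect_true(all(diff(fit$predicted_probs) > 0))
  expect_true(all(fit$predicted_probs > 0 & fit$predicted_probs < 1))
  # declining suppression is picked up with a negative slope
  fit_s <- fit_time_trend(long, "suppression")
  expect_lt(fit_s$coef_time, 0)
  expect_true(all(diff(fit_s$predicted_probs) < 0))
  # random-intercept variant runs and agrees in sign
  fit_re <- fit_time_trend(long, "engagement", random_effects = TRUE)
  expect_gt(fit_re$coef_time, 0)
})

test_that("degenerate trend inputs error clearly", {
  long <- make_long(c(3, 3, 3), 5)
  expect_error(fit_time_trend(long[long$time == 0, ], "engagement"), "distinct time")
  long$engagement <- long$engagement * 2L
  expect_error(fit_time_trend(long, "engagement"), "binary")
})

corr_frame <- function(n = 400, seed = 61, beta_age = 0) {
  set.seed(seed)
  df <- tibble::tibble(
    id = sprintf("p%04d", 1:n),
    age_years = stats::runif(n, 18, 70),
    race = sample(c("white", "black", "other"), n, TRUE, c(0.2, 0.7, 0.1)),
    ethnicity = sample(c("non_hispanic", "hispanic"), n, TRUE, c(0.95, 0.05)),
    gender = sample(c("female", "male"), n, TRUE),
    relationship = sample(c("no_primary_partner", "primary_partner"), n, TRUE),
    employment = sample(c("unemployed", "employed"), n, TRUE),
    housing = sample(c("stable", "unstable"), n, TRUE, c(0.85, 0.15)),
    insurance = sample(c("insured", "uninsured"), n, TRUE, c(0.9, 0.1)),
    site = sample(c("A", "B", "C", "D"), n, TRUE),
    enrollment_category = sample(c("A", "B"), n, TRUE, c(0.58, 0.42)),
    baseline_retention = stats::rbinom(n, 1, 0.4)
  )
  eta <- -0.5 + 0.6 * df$baseline_retention + beta_age * (df$age_years - 44)
  df$retention <- stats::rbinom(n, 1, stats::plogis(eta))
  df$engagement <- df$retention
  df$suppression <- df$retention
  df$baseline_engagement <- df$baseline_retention
  df$baseline_suppression <- df$baseline_retention
  df
}

test_that("benchmark correlates recover a null covariate as null and a planted effect with coverage", {
  df <- corr_frame(n = 500, seed = 8)
  fit <- fit_benchmark_correlates(df, "retention")
  age_row <- fit[fit$term == "age_years", ]
  expect_lt(abs(age_row$coef), 3 * age_row$se)   # true age effect is zero
  expect_true(all(c("baseline_retention", "siteB", "enrollment_categoryA") %in% fit$term))
  expect_equal(unique(fit$model), "benchmark")

  # planted age effect: 95% CI coverage across replicates
  hits <- 0; reps <- 60
  for (r in 1:reps) {
    d <- corr_frame(n = 400, seed = 1000 + r, beta_age = 0.03)
    f <- fit_benchmark_correlates(d, "retention")
    a <- f[f$term == "age_years", ]
    if (abs(a$coef - 0.03) <= 1.96 * a$se) hits <- hits + 1
  }
  cover <- hits / reps
  expect_gt(cover, 0.95 - 3 * sqrt(0.95 * 0.05 / reps))
})

test_that("an outcome equal to its baseline measure loads entirely on the baseline term", {
  df <- corr_frame(n = 400, seed = 15)
  df$retention <- df$baseline_retention
  fit <- fit_benchmark_correlates(df, "retention")
  b <- fit[fit$term == "baseline_retention", ]
  expect_gt(b$coef, 3)            # near-separation scale dominance
  others <- fit[!fit$term %in% c("(Intercept)", "baseline_retention"), ]
  expect_true(all(abs(others$coef) < 2))
})

test_that("a site with no positive outcomes is dropped and recorded", {
  df <- corr_frame(n = 400, seed = 33)
  df$retention[df$site == "D"] <- 0L
  fit <- fit_benchmark_correlates(df, "retention")
  expect_false("siteD" %in% fit$term)
  expect_true("site:D" %in% attr(fit, "dropped_levels"))
})

test_that("add-one fits report only the extra term on the complete-case subset", {
  df <- corr_frame(n = 450, seed = 44)
  df$acceptability <- stats::runif(nrow(df), 0, 4)      # unrelated by construction
  df$acceptability[1:60] <- NA
  fit <- fit_add_one(df, "retention", "acceptability")
  expect_equal(nrow(fit), 1)
  expect_equal(fit$term, "acceptability")
  expect_equal(fit$model, "add_one")
  expect_equal(fit$n_obs, nrow(df) - 60)
  expect_lt(abs(fit$coef), 3 * fit$se)

  full <- fit_add_one(df[!is.na(df$acceptability), ], "retention", "acceptability")
  expect_gt(full$n_obs, fit$n_obs - 1)

  df$age_copy <- df$age_years
  expect_error(fit_add_one(df, "retention", "age_copy"), "collinear")
  df$all_na <- NA_real_
  expect_error(fit_add_one(df, "retention", "all_na"), "missing")
})
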