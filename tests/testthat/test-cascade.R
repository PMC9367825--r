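anchor <- as.Date("2019-03-01")
cfg <- cascade_config()

test_that("engagement window boundaries follow the 12-month +/- 1-month rule", {
  expect_true(classify_engagement(tests_at(anchor, 100), anchor, cfg))
  expect_false(classify_engagement(tests_at(anchor, integer(0)), anchor, cfg))
  expect_true(classify_engagement(tests_at(anchor, 390), anchor, cfg))
  expect_false(classify_engagement(tests_at(anchor, 391), anchor, cfg))
  # the anchor-day test itself never counts
  expect_false(classify_engagement(tests_at(anchor, 0), anchor, cfg))
  # baseline lookback covers the 12 months before enrollment
  expect_true(classify_engagement(tests_at(anchor, -200), anchor, cfg, lookback = TRUE))
  expect_false(classify_engagement(tests_at(anchor, -361), anchor, cfg, lookback = TRUE))
})

test_that("retention needs two in-window tests at least 90 days apart", {
  expect_true(classify_retention(tests_at(anchor, c(10, 100)), anchor, cfg))
  expect_false(classify_retention(tests_at(anchor, c(10, 99)), anchor, cfg))
  five <- tests_at(anchor, c(20, 40, 60, 80, 110))   # max pairwise gap exactly 90
  expect_true(classify_retention(five, anchor, cfg))
  expect_false(classify_retention(tests_at(anchor, 100), anchor, cfg))
})

test_that("suppression uses the most recent test in the reporting window, strictly below 200", {
  rep6 <- anchor + 180
  expect_true(classify_suppression(tests_at(anchor, 180, 40L), rep6, cfg))
  expect_false(classify_suppression(tests_at(anchor, 180, 200L), rep6, cfg))
  both <- tests_at(anchor, c(160, 190), c(500L, 100L))   # -20 d and +10 d around report
  expect_true(classify_suppression(both, rep6, cfg))
  expect_false(classify_suppression(tests_at(anchor, 100, 40L), rep6, cfg))  # outside window
})

test_that("raising the suppression threshold never decreases the suppressed count", {
  set.seed(5)
  streams <- replicate(200, random_test_stream(), simplify = FALSE)
  counts <- vapply(c(50, 200, 1000, 10000), function(thr) {
    c2 <- cascade_config(suppression_threshold = thr)
    sum(vapply(streams, function(s)
      classify_suppression(tests_at(anchor, s$days, s$vls), anchor + 180, c2), logical(1)))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("classifications agree with an exhaustive window scan on random streams", {
  set.seed(99)
  for (i in 1:1000) {
    s <- random_test_stream()
    tt <- tests_at(anchor, s$days, s$vls)
    for (tp in c("t0", "t1", "t2")) {
      o <- oracle_cascade(s$days, s$vls, tp)
      if (tp == "t0") {
        got <- c(classify_engagement(tt, anchor, cfg, lookback = TRUE),
                 classify_retention(tt, anchor, cfg, lookback = TRUE),
                 classify_suppression(tt, anchor, cfg))
      } else {
        h <- if (tp == "t1") 180L else 360L
        got <- c(classify_engagement(tt, anchor, cfg, horizon_days = h),
                 classify_retention(tt, anchor, cfg, horizon_days = h),
                 classify_suppression(tt, anchor + h, cfg))
      }
      expect_identical(got, unlist(o, use.names = FALSE))
    }
  }
})

test_that("retention implies engagement at every timepoint on generated cohorts", {
  sim <- generate_cohort(cohort_config(n_participants = 150, seed = 88))
  st <- cascade_statuses(sim$participants, sim$lab_tests)
  expect_true(all(st$engaged[st$retained]))
  expect_true(all(st$n_tests_in_window >= 0))
})

test_that("cohort tabulation reproduces the enrolled-denominator proportions", {
  n <- 781
  make_tp <- function(tp, n_eng, n_ret, n_sup) tibble::tibble(
    participant_id = sprintf("P%04d", 1:n), timepoint = tp,
    engaged = seq_len(n) <= n_eng,
    retained = seq_len(n) <= n_ret,           # retained are a subset of engaged
    suppressed = seq_len(n) <= n_sup,
    n_tests_in_window = as.integer(seq_len(n) <= n_eng)
  )
  st <- make_tp("t0", 548, 326, 485)
  tab <- cascade_table(st)
  expect_equal(tab$engaged, 548)
  expect_equal(tab$retained, 326)
  expect_equal(tab$suppressed, 485)
  expect_equal(round(100 * tab$engaged_prop), 70)
  expect_equal(round(100 * tab$retained_prop), 42)
  expect_equal(round(100 * tab$suppressed_prop), 62)
  expect_true(all(tab$engaged_prop >= 0 & tab$engaged_prop <= 1))

  expect_error(cascade_table(st[0, ]), "empty")
  expect_error(cascade_table(rbind(st, st[1, ])), "duplicate")

  # complete-case switch changes the denominator to tested participants
  cc <- cascade_table(st, cascade_config(missing_rule = "complete_case"))
  expect_equal(cc$n, 548)
  expect_equal(cc$engaged_prop, 1)
})
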