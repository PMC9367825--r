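scr <- as.Date("2019-06-01")
base_record <- function(...) {
  utils::modifyList(list(
    age_years = 40, resident = TRUE, plans_to_move = FALSE, english_ok = TRUE,
    confirmed_hiv = TRUE, in_other_study = FALSE, institutionalized = FALSE,
    missed_visits_6mo = 0L, risk_factors = character(),
    diagnosis_date = scr - 2000, screening_date = scr
  ), list(...))
}

test_that("Category A fires on care gaps, consecutive detectable pairs, and missed visits", {
  nine_months_ago <- tests_at(scr, -270, 40L)
  a <- screen_category_a(base_record(), nine_months_ago)
  expect_true(a$qualifies)
  expect_true("NO_VL_8MO" %in% a$reasons)

  pair <- tests_at(scr, c(-120, -30), c(250L, 300L))   # 90 days apart, both detectable
  a2 <- screen_category_a(base_record(), pair)
  expect_true("TWO_DETECTABLE_90D" %in% a2$reasons)

  # all three clauses false: detectable pair only 60 days apart, recent test, 1 missed visit
  close_pair <- tests_at(scr, c(-120, -60), c(250L, 300L))
  a3 <- screen_category_a(base_record(missed_visits_6mo = 1L), close_pair)
  expect_false(a3$qualifies)

  a4 <- screen_category_a(base_record(missed_visits_6mo = 2L), tests_at(scr, -30, 40L))
  expect_true("MISSED_2_VISITS" %in% a4$reasons)

  # an intervening suppressed test breaks "consecutive"
  broken <- tests_at(scr, c(-200, -100, -50), c(250L, 40L, 300L))
  a5 <- screen_category_a(base_record(), broken)
  expect_false("TWO_DETECTABLE_90D" %in% a5$reasons)
  expect_error(screen_category_a(base_record(), tests_at(scr, c(-30, -100))), "sorted")
})

test_that("Category B fires on recent untreated diagnosis or a self-reported risk factor", {
  no_tests <- tests_at(scr, integer(0))
  b <- screen_category_b(base_record(diagnosis_date = scr - 150), no_tests)
  expect_true("NEW_DX_NOT_IN_CARE" %in% b$reasons)

  # diagnosed 6 years ago, engaged, no risk factors
  b2 <- screen_category_b(base_record(), tests_at(scr, -30, 40L))
  expect_false(b2$qualifies)

  b3 <- screen_category_b(base_record(risk_factors = "unstable_housing"), tests_at(scr, -30, 40L))
  expect_true("RISK_FACTOR" %in% b3$reasons)

  # tested since diagnosis => in care
  b4 <- screen_category_b(base_record(diagnosis_date = scr - 150), tests_at(scr, -100, 40L))
  expect_false("NEW_DX_NOT_IN_CARE" %in% b4$reasons)
  expect_error(screen_category_b(base_record(diagnosis_date = scr + 10), no_tests), "diagnosis_date")
})

test_that("gating criteria and category precedence compose correctly", {
  qualifying_labs <- tests_at(scr, -270, 40L)          # Category A via care gap
  expect_false(check_eligibility(base_record(age_years = 17), qualifying_labs)$eligible)
  expect_false(check_eligibility(base_record(plans_to_move = TRUE), qualifying_labs)$eligible)
  expect_false(check_eligibility(base_record(confirmed_hiv = FALSE), qualifying_labs)$eligible)
  expect_false(check_eligibility(base_record(institutionalized = TRUE), qualifying_labs)$eligible)

  ok <- check_eligibility(base_record(), qualifying_labs)
  expect_true(ok$eligible)
  expect_equal(ok$category, "A")
  expect_gt(length(ok$reasons), 0)

  # B only: in care recently, but a risk factor
  b_only <- check_eligibility(base_record(risk_factors = "incarceration_history"),
                              tests_at(scr, -30, 40L))
  expect_equal(b_only$category, "B")

  # both A and B hold => A takes precedence
  both <- check_eligibility(base_record(risk_factors = "unstable_housing"), qualifying_labs)
  expect_equal(both$category, "A")

  neither <- check_eligibility(base_record(), tests_at(scr, -30, 40L))
  expect_false(neither$eligible)
  expect_equal(neither$category, "none")
})

test_that("adding a risk factor never flips an eligible record to ineligible", {
  set.seed(77)
  for (i in 1:200) {
    rr <- random_screening_record()
    before <- check_eligibility(rr$rec, rr$labs)
    rec2 <- rr$rec
    rec2$risk_factors <- union(rec2$risk_factors, sample(RISK_FACTORS, 1))
    after <- check_eligibility(rec2, rr$labs)
    if (before$eligible) expect_true(after$eligible)
  }
})

test_that("eligibility matches an independent clause-by-clause evaluator on random records", {
  set.seed(123)
  for (i in 1:1000) {
    rr <- random_screening_record()
    got <- check_eligibility(rr$rec, rr$labs)
    want <- oracle_eligibility(rr$rec, rr$labs)
    expect_equal(got$eligible, want$eligible)
    expect_equal(got$category, want$category)
    if (got$eligible) expect_gt(length(got$reasons), 0)
  }
})

test_that("cohort screening reports the A/B split on generated data", {
  sim <- generate_cohort(cohort_config(n_participants = 200, seed = 55))
  rep <- screen_cohort(sim$participants, sim$lab_tests)
  expect_equal(nrow(rep), 200)
  expect_true(all(rep$category %in% c("A", "B", "none")))
  expect_true(all(rep$eligible == (rep$category != "none")))
  expect_true(all(nchar(rep$reasons[rep$eligible]) > 0))
})
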