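test_that("identical seed and configuration give bit-identical cohorts", {
  cfg <- cohort_config(n_participants = 50, seed = 12)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  one <- generate_cohort(cohort_config(n_participants = 1, seed = 3))
  expect_identical(one, generate_cohort(cohort_config(n_participants = 1, seed = 3)))
  expect_false(identical(a, generate_cohort(cohort_config(n_participants = 50, seed = 13))))
})

test_that("configuration invariants are enforced with informative errors", {
  bad <- default_marginals()
  bad$race <- c(black = 0.6, white = 0.6)
  expect_error(cohort_config(marginals = bad), "race")
  expect_error(cohort_config(n_participants = 0), "n_participants")
  expect_error(cohort_config(category_a_share = 1.2), "category_a_share")
  expect_error(cohort_config(p_engaged = c(0.5, 0.9, 0.8)), "nest")
  expect_equal(cohort_config(enforce_quota = TRUE)$category_a_share, 0.80)
})

test_that("a full-size cohort reproduces the configured marginals within 3-sigma binomial bounds", {
  cfg <- cohort_config(n_participants = 781, seed = 7)
  sim <- generate_cohort(cfg)
  p <- sim$participants
  expect_equal(nrow(p), 781)
  expect_true(all(p$age_years >= 18))
  expect_true(all(p$diagnosis_date <= p$enrollment_date))

  black_share <- mean(p$race == "black")
  expect_lt(abs(black_share - 0.892), 0.03)

  within3 <- function(obs_share, prob, n = 781) {
    abs(obs_share - prob) <= 3 * sqrt(prob * (1 - prob) / n)
  }
  m <- cfg$marginals
  expect_true(within3(mean(p$gender == "male"), m$gender[["male"]]))
  expect_true(within3(mean(p$employment == "unemployed"), m$employment[["unemployed"]]))
  expect_true(within3(mean(p$housing == "unstable"), m$housing[["unstable"]]))
  expect_true(within3(mean(p$insurance == "insured"), m$insurance[["insured"]]))
  expect_true(within3(mean(p$enrollment_category == "A"), 0.58))

  # lab streams stay inside the simulated observation window
  rel <- as.integer(sim$lab_tests$test_date -
                    p$enrollment_date[match(sim$lab_tests$participant_id, p$id)])
  expect_true(all(rel >= -360 & rel <= 390))
})

test_that("certain suppression propagates through the cascade classifier", {
  cfg <- cohort_config(n_participants = 120, seed = 21,
                       p_suppressed_given_visit = c(1, 1, 1))
  sim <- generate_cohort(cfg)
  st <- cascade_statuses(sim$participants, sim$lab_tests)
  # whoever has a test in a reporting window classifies suppressed there
  for (tp in c("t0", "t1", "t2")) {
    sub <- st[st$timepoint == tp, ]
    has_report_test <- vapply(seq_len(nrow(sub)), function(i) {
      pid <- sub$participant_id[i]
      enr <- sim$participants$enrollment_date[sim$participants$id == pid]
      rd <- enr + c(t0 = 0, t1 = 180, t2 = 360)[[tp]]
      any(abs(as.integer(sim$lab_tests$test_date[sim$lab_tests$participant_id == pid] - rd)) <= 30)
    }, logical(1))
    expect_equal(sub$suppressed, has_report_test)
  }
})

test_that("raising the incentive visit boost never lowers any participant's lab count", {
  n <- 1000
  count_tests <- function(boost) {
    sim <- generate_cohort(cohort_config(n_participants = n, seed = 99,
                                         incentive_visit_boost = boost))
    tab <- table(factor(sim$lab_tests$participant_id,
                        levels = sim$participants$id))
    as.integer(tab)
  }
  lo <- count_tests(0.5); mid <- count_tests(1.5); hi <- count_tests(3.0)
  expect_true(all(mid >= lo))
  expect_true(all(hi >= mid))
  expect_gt(mean(hi), mean(lo))
})

test_that("cohorts generated with known engagement probabilities hand off to the cascade within binomial bounds", {
  probs <- c(0.60, 0.75, 0.90)
  sim <- generate_cohort(cohort_config(n_participants = 781, seed = 17, p_engaged = probs))
  st <- cascade_statuses(sim$participants, sim$lab_tests)
  tab <- cascade_table(st)
  for (j in 1:3) {
    bound <- 3 * sqrt(probs[j] * (1 - probs[j]) / 781)
    expect_lt(abs(tab$engaged_prop[j] - probs[j]), bound)
  }
})

test_that("cost-input generation passes literals through and draws valid random profiles", {
  lit <- tibble::tibble(clinic_id = "A", n_clients = 214L, n_contacts = 642L,
                        client_costs = 15515, staff_costs = 164781,
                        materials_costs = 216614, net_suppressed = 22L)
  ci <- generate_cost_inputs(lit, seed = 4)
  expect_equal(total_cost(ci, "societal"), 396910.00)

  zero <- tibble::tibble(clinic_id = "Z", n_clients = 10L, n_contacts = 10L,
                         client_costs = 0, staff_costs = 0, materials_costs = 0,
                         net_suppressed = 0L)
  expect_equal(total_cost(generate_cost_inputs(zero, 1), "societal"), 0)

  prof <- tibble::tibble(clinic_id = c("R1", "R2"), n_clients = c(150L, 80L),
                         n_contacts = c(500L, 300L))
  rci <- generate_cost_inputs(prof, seed = 8)
  expect_true(all(rci$client_costs >= 0 & rci$staff_costs >= 0 & rci$materials_costs >= 0))
  expect_true(all(rci$n_clients >= 1))
  res <- cost_utility_analysis(rci[rci$net_suppressed > 0, ])  # econ smoke test
  expect_true(all(res$Q_total > 0))
})
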