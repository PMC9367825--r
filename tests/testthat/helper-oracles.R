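# Independent brute-force oracles. These re-derive the classification and
# estimation rules from first principles, deliberately not sharing code with
# the package implementation.

# --- eligibility oracle ------------------------------------------------

oracle_eligibility <- function(rec, labs) {
  day <- function(d) as.integer(rec$screening_date - d)
  gate_ok <- rec$confirmed_hiv && rec$resident && !rec$plans_to_move &&
    rec$age_years >= 18 && rec$english_ok &&
    !isTRUE(rec$in_other_study) && !isTRUE(rec$institutionalized)
  if (!gate_ok) return(list(eligible = FALSE, category = "none"))

  # Category A, clause by clause
  no_vl_8mo <- TRUE
  for (d in as.list(labs$test_date)) {
    if (day(d) >= 0 && day(d) < 240) no_vl_8mo <- FALSE
  }
  two_detectable <- FALSE
  pre <- labs[labs$test_date <= rec$screening_date, ]
  pre <- pre[order(pre$test_date), ]
  if (nrow(pre) >= 2) {
    for (i in 1:(nrow(pre) - 1)) {
      gap <- as.integer(pre$test_date[i + 1] - pre$test_date[i])
      if (pre$viral_load[i] >= 200 && pre$viral_load[i + 1] >= 200 && gap >= 90)
        two_detectable <- TRUE
    }
  }
  cat_a <- no_vl_8mo || two_detectable || rec$missed_visits_6mo >= 2
  if (cat_a) return(list(eligible = TRUE, category = "A"))

  # Category B
  dxd <- as.integer(rec$screening_date - rec$diagnosis_date)
  new_dx <- !is.na(dxd) && dxd > 90 && dxd <= 360
  tested_since <- FALSE
  for (d in as.list(labs$test_date)) {
    if (d >= rec$diagnosis_date && d <= rec$screening_date) tested_since <- TRUE
  }
  cat_b <- (new_dx && !tested_since) || length(rec$risk_factors) > 0
  if (cat_b) return(list(eligible = TRUE, category = "B"))
  list(eligible = FALSE, category = "none")
}

random_screening_record <- function() {
  scr <- as.Date("2019-06-01")
  n_tests <- sample(0:6, 1)
  labs <- data.frame(
    test_date = scr - sample(0:500, n_tests),
    viral_load = sample(c(40L, 150L, 250L, 5000L), n_tests, replace = TRUE)
  )
  labs <- labs[order(labs$test_date), , drop = FALSE]
  list(
    rec = list(
      age_years = sample(16:70, 1),
      resident = runif(1) < 0.9, plans_to_move = runif(1) < 0.1,
      english_ok = runif(1) < 0.95, confirmed_hiv = runif(1) < 0.95,
      in_other_study = runif(1) < 0.05, institutionalized = runif(1) < 0.05,
      missed_visits_6mo = sample(0:4, 1),
      risk_factors = sample(cascadecea::RISK_FACTORS, sample(0:2, 1)),
      diagnosis_date = scr - sample(30:2000, 1),
      screening_date = scr
    ),
    labs = tibble::as_tibble(labs)
  )
}

# --- cascade oracle ----------------------------------------------------

# exhaustive scan over tests / pairs of tests, windows written out longhand
oracle_cascade <- function(days, vls, timepoint, threshold = 200) {
  horizon <- c(t1 = 180L, t2 = 360L)
  if (timepoint == "t0") {
    in_win <- days >= -360 & days <= -1
    report_day <- 0L
  } else {
    h <- horizon[[timepoint]]
    in_win <- days >= 1 & days <= h + 30
    report_day <- h
  }
  eng <- sum(in_win) >= 1
  ret <- FALSE
  w <- days[in_win]
  if (length(w) >= 2) {
    for (i in seq_along(w)) for (j in seq_along(w)) {
      if (abs(w[i] - w[j]) >= 90) ret <- TRUE
    }
  }
  near <- which(days >= report_day - 30 & days <= report_day + 30)
  sup <- FALSE
  if (length(near)) {
    best <- near[1]
    for (k in near) if (days[k] >= days[best]) best <- k
    sup <- vls[best] < threshold
  }
  list(engaged = eng, retained = ret, suppressed = sup)
}

random_test_stream <- function() {
  n <- sample(0:8, 1)
  list(days = sort(sample(-400:420, n)),
       vls = sample(c(40L, 199L, 200L, 8000L), n, replace = TRUE))
}

# --- logistic MLE oracle ----------------------------------------------

# maximises the Bernoulli-logit likelihood directly with optim (BFGS on an
# explicitly coded negative log-likelihood)
oracle_logit_mle <- function(y, X) {
  nll <- function(beta) {
    eta <- as.vector(X %*% beta)
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  gr <- function(beta) {
    eta <- as.vector(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    as.vector(t(X) %*% (p - y))
  }
  fit <- optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  fit$par
}

# lab-test tibble shorthand used across cascade/incentive tests
tests_at <- function(anchor, days, vls = rep(50L, length(days))) {
  tibble::tibble(test_date = as.Date(anchor) + days, viral_load = as.integer(vls))
}
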