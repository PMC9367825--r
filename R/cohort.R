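#' Default categorical marginal distributions
#'
#' Probability vectors for each categorical participant characteristic,
#' derived from the observed baseline composition of a four-clinic Southern
#' US cohort of persons living with HIV (counts normalised to
#' probabilities). Site shares reflect relative clinic capacity.
#'
#' @return named list of named probability vectors
#' @export
default_marginals <- function() {
  norm <- function(x) x / sum(x)
  lapply(list(
    race = c(black = 686, white = 63, other = 12, multiracial = 8),
    ethnicity = c(non_hispanic = 749, hispanic = 12),
    gender = c(male = 412, female = 347, transgender_nonbinary = 16),
    sexual_orientation = c(heterosexual = 500, glb_other = 238),
    relationship = c(no_primary_partner = 642, primary_partner = 135),
    education = c(less_than_hs = 245, hs_ged_some_college = 398, postsecondary = 105),
    employment = c(unemployed = 331, employed = 290, disabled = 121, other = 35),
    income_band = c(under_5k = 273, `5k_9999` = 99, `10k_14999` = 76,
                    `15k_19999` = 45, `20k_plus` = 149),
    housing = c(stable = 672, unstable = 105),
    incarceration = c(none = 678, recent = 90),
    insurance = c(insured = 678, uninsured = 78),
    years_hiv = c(over_5 = 487, `1_to_5` = 178, under_1 = 62),
    site = c(A = 0.35, B = 0.20, C = 0.30, D = 0.15)
  ), norm)
}

#' Synthetic cohort configuration
#'
#' Defines the study conditions the generator emulates: sample size,
#' categorical marginals, the Category A / B enrollment split, window-level
#' engagement probabilities at baseline and the 6- and 12-month timepoints,
#' per-visit suppression probabilities, routine-lab visit rates and the
#' multiplicative effect of incentive eligibility on them, and the
#' enrollment window.
#'
#' @param n_participants cohort size (>= 1)
#' @param seed master integer seed; per-participant substreams are derived
#'   from it so edits stay local
#' @param marginals named list of categorical probability vectors (each must
#'   sum to 1 within 1e-9)
#' @param category_a_share probability of Category A enrollment (observed
#'   share by default); `enforce_quota = TRUE` switches to the >= 80%
#'   protocol quota
#' @param enforce_quota use the protocol quota instead of the observed share
#' @param visit_rate_base expected routine (non-reporting) lab visits per
#'   year absent incentives
#' @param incentive_visit_boost multiplicative effect of incentive
#'   eligibility on the post-enrollment routine visit rate (>= 0)
#' @param p_engaged window-level engagement probabilities at t0/t1/t2 (must
#'   be non-decreasing from t1 to t2 since the windows nest)
#' @param p_suppressed_given_visit probability that a viral-load test drawn
#'   at t0/t1/t2 reads suppressed
#' @param p_report_attend probability an engaged participant completes the
#'   lab in the +/- 1-month reporting window
#' @param vl_suppressed,vl_detectable copies/mL values drawn for suppressed
#'   and detectable results (clearly on either side of the 200 threshold)
#' @param enrollment_window Date range enrollment dates are drawn from
#' @return list of class `cohort_config`
#' @export
cohort_config <- function(n_participants = 781L,
                          seed = 1L,
                          marginals = default_marginals(),
                          category_a_share = 0.58,
                          enforce_quota = FALSE,
                          visit_rate_base = 1.0,
                          incentive_visit_boost = 1.5,
                          p_engaged = c(t0 = 0.70, t1 = 0.85, t2 = 0.93),
                          p_suppressed_given_visit = c(t0 = 0.62, t1 = 0.58, t2 = 0.385),
                          p_report_attend = 0.95,
                          vl_suppressed = 50L,
                          vl_detectable = 10000L,
                          enrollment_window = as.Date(c("2018-08-01", "2019-10-31"))) {
  if (n_participants < 1) stop_data("n_participants must be >= 1")
  if (category_a_share < 0 || category_a_share > 1) stop_data("category_a_share must be in [0,1]")
  if (visit_rate_base < 0 || incentive_visit_boost < 0)
    stop_data("visit rates must be non-negative")
  for (v in names(marginals)) {
    p <- marginals[[v]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop_data("marginal for '%s' is not a probability vector (sums to %.12f)", v, sum(p))
  }
  if (length(p_engaged) != 3 || any(p_engaged < 0 | p_engaged > 1))
    stop_data("p_engaged must be 3 probabilities")
  if (p_engaged[2] > p_engaged[3])
    stop_data("p_engaged at t1 cannot exceed t2: the windows nest")
  if (enforce_quota) category_a_share <- 0.80
  structure(list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    marginals = marginals, category_a_share = category_a_share,
    visit_rate_base = visit_rate_base, incentive_visit_boost = incentive_visit_boost,
    p_engaged = unname(p_engaged),
    p_suppressed_given_visit = unname(p_suppressed_given_visit),
    p_report_attend = p_report_attend,
    vl_suppressed = as.integer(vl_suppressed), vl_detectable = as.integer(vl_detectable),
    enrollment_window = enrollment_window
  ), class = "cohort_config")
}

# one draw from a categorical marginal
draw_cat <- function(p) sample(names(p), 1L, prob = p)

vl_draw <- function(n, p_supp, cfg) {
  ifelse(stats::runif(n) < p_supp, cfg$vl_suppressed, cfg$vl_detectable)
}

# lab-test stream for one participant; all draws happen in a fixed order so
# that the visit-count quantile coupling (qpois on a shared uniform) makes
# the stream monotone in incentive_visit_boost
participant_labs <- function(cfg, enr) {
  p_eng <- cfg$p_engaged
  p_sup <- cfg$p_suppressed_given_visit
  days <- integer(0); vl <- integer(0)
  add <- function(d, v) { days <<- c(days, d); vl <<- c(vl, v) }

  eng0 <- stats::runif(1) < p_eng[1]
  k0 <- 1L + stats::qpois(stats::runif(1), cfg$visit_rate_base)
  eng2 <- stats::runif(1) < p_eng[3]
  eng1 <- eng2 && stats::runif(1) < (if (p_eng[3] > 0) p_eng[2] / p_eng[3] else 0)
  r1 <- eng1 && stats::runif(1) < cfg$p_report_attend
  r2 <- eng2 && stats::runif(1) < cfg$p_report_attend
  lam_post <- cfg$visit_rate_base * cfg$incentive_visit_boost
  k1 <- stats::qpois(stats::runif(1), lam_post * 149 / 360)
  k2 <- stats::qpois(stats::runif(1), lam_post * 119 / 360)

  if (eng0) add(sort(sample(-360:-1, k0)), vl_draw(k0, p_sup[1], cfg))
  add(0L, vl_draw(1, p_sup[1], cfg))             # enrollment-day baseline test
  if (eng1) {
    if (r1) add(180L + sample(-30:30, 1L), vl_draw(1, p_sup[2], cfg))
    if (k1 > 0) add(sample(1:149, k1), vl_draw(k1, p_sup[2], cfg))
    if (!r1 && k1 == 0) add(sample(1:149, 1L), vl_draw(1, p_sup[2], cfg))
  }
  if (eng2) {
    if (r2) add(360L + sample(-30:30, 1L), vl_draw(1, p_sup[3], cfg))
    if (k2 > 0) add(sample(211:329, k2), vl_draw(k2, p_sup[3], cfg))
    if (!eng1 && !r2 && k2 == 0) add(sample(211:329, 1L), vl_draw(1, p_sup[3], cfg))
  }
  ord <- order(days)
  tibble::tibble(test_date = enr + days[ord], viral_load = as.integer(vl[ord]))
}

participant_row <- function(cfg, i) {
  m <- cfg$marginals
  enr <- cfg$enrollment_window[1] +
    sample.int(as.integer(diff(cfg$enrollment_window)) + 1L, 1L) - 1L
  age <- max(18, stats::rnorm(1, 42.4, 12.2))
  cat_a <- stats::runif(1) < cfg$category_a_share
  vars <- lapply(m, draw_cat)
  yrs <- switch(vars$years_hiv,
                under_1 = stats::runif(1, 0.3, 1),
                `1_to_5` = stats::runif(1, 1, 5),
                over_5 = stats::runif(1, 5, 20))
  gender_group <- if (vars$gender == "transgender_nonbinary") "gender_minority" else vars$gender

  # survey items; missingness rates chosen to match per-instrument
  # complete-case counts of the emulated cohort
  latent_acc <- stats::rnorm(1, 2.5, 0.9)
  acc_raw <- pmin(4, pmax(0, round(latent_acc + stats::rnorm(4, 0, 0.7))))
  acc_raw[4] <- 4 - acc_raw[4]                    # stored as administered (reversed wording)
  acc_raw[stats::runif(4) < 0.05] <- NA
  auditc <- if (stats::runif(1) < 0.124) NA_integer_ else min(12L, stats::rpois(1, 2))
  phq <- sample(0:3, 9, replace = TRUE, prob = c(0.45, 0.35, 0.15, 0.05))
  if (stats::runif(1) < 0.154) phq <- rep(NA_integer_, 9)
  case_score <- if (stats::runif(1) < 0.207) NA_real_ else
    min(16, max(3, round(stats::rnorm(1, 11.8, 3.6))))
  stig <- sample(1:5, 4, replace = TRUE, prob = c(0.01, 0.02, 0.05, 0.20, 0.72))
  if (stats::runif(1) < 0.082) stig <- rep(NA_integer_, 4)
  missed <- stats::rpois(1, if (cat_a) 1.2 else 0.3)

  row <- tibble::tibble(
    id = sprintf("P%05d", i),
    enrollment_date = enr,
    age_years = age,
    enrollment_category = if (cat_a) "A" else "B",
    diagnosis_date = enr - as.integer(round(yrs * 360)),
    gender_group = gender_group,
    resident = TRUE, plans_to_move = FALSE, english_ok = TRUE,
    confirmed_hiv = TRUE, in_other_study = FALSE, institutionalized = FALSE,
    missed_visits_6mo = missed,
    behavioral_health_12mo = stats::runif(1) < 0.25,
    accept_1 = acc_raw[1], accept_2 = acc_raw[2], accept_3 = acc_raw[3], accept_4 = acc_raw[4],
    auditc_score = auditc,
    case_score = case_score
  )
  for (v in names(vars)) row[[v]] <- vars[[v]]
  row$unstable_housing <- row$housing == "unstable"
  row$unemployed_3mo <- row$employment == "unemployed" && stats::runif(1) < 0.8
  row$incarceration_history <- row$incarceration == "recent"
  for (j in 1:9) row[[paste0("phq9_", j)]] <- phq[j]
  for (j in 1:4) row[[paste0("stigma_", j)]] <- stig[j]
  row
}

#' Generate a seeded synthetic cohort
#'
#' Produces a participants table and a dated viral-load test stream per
#' participant covering 12 months before through 13 months after
#' enrollment. Identical seed and configuration give bit-identical output;
#' each participant draws from an independently derived substream.
#'
#' @param config a [cohort_config()]
#' @return list with `participants` and `lab_tests` tibbles
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  p_rows <- vector("list", config$n_participants)
  l_rows <- vector("list", config$n_participants)
  for (i in seq_len(config$n_participants)) {
    set.seed(substream_seed(config$seed, i))
    p_rows[[i]] <- participant_row(config, i)
    labs <- participant_labs(config, p_rows[[i]]$enrollment_date)
    labs$participant_id <- p_rows[[i]]$id
    l_rows[[i]] <- labs[c("participant_id", "test_date", "viral_load")]
  }
  list(participants = dplyr::bind_rows(p_rows),
       lab_tests = dplyr::bind_rows(l_rows))
}

#' Generate per-clinic cost inputs
#'
#' Builds a [cost_inputs()] table from clinic profiles. Profiles that carry
#' explicit component costs (`client_costs`, `staff_costs`,
#' `materials_costs`) and `net_suppressed` are passed through unchanged;
#' otherwise components are drawn on realistic per-client scales
#' (log-uniform, spanning the order-of-magnitude spread seen across real
#' clinics) and net suppression as a binomial share of clients.
#'
#' @param clinic_profiles tibble with `clinic_id`, `n_clients`, `n_contacts`
#'   and optionally explicit cost columns
#' @param seed integer seed
#' @return a [cost_inputs()] tibble
#' @export
generate_cost_inputs <- function(clinic_profiles, seed = 1L) {
  set.seed(seed)
  n <- nrow(clinic_profiles)
  has <- function(col) col %in% names(clinic_profiles) && !anyNA(clinic_profiles[[col]])
  lunif <- function(lo, hi) exp(stats::runif(n, log(lo), log(hi)))
  client <- if (has("client_costs")) clinic_profiles$client_costs else
    round_cents(clinic_profiles$n_clients * lunif(5, 80))
  staff <- if (has("staff_costs")) clinic_profiles$staff_costs else
    round_cents(clinic_profiles$n_clients * lunif(50, 800))
  materials <- if (has("materials_costs")) clinic_profiles$materials_costs else
    round_cents(clinic_profiles$n_clients * lunif(10, 1000))
  net <- if (has("net_suppressed")) clinic_profiles$net_suppressed else
    stats::rbinom(n, clinic_profiles$n_clients, stats::runif(n, 0.04, 0.10))
  cost_inputs(clinic_profiles$clinic_id, clinic_profiles$n_clients,
              clinic_profiles$n_contacts, client, staff, materials, net)
}
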