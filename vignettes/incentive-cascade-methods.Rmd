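---
title: "Methods: evaluating conditional financial incentives on the HIV care continuum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating conditional financial incentives on the HIV care continuum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cascadecea)
```

## What this package evaluates

Conditional financial incentive programs pay persons living with HIV (PLWH)
small amounts for completing care milestones — here USD10 per completed lab
visit (at most 4) and USD50 for a suppressed viral load at each of the 6-
and 12-month reporting timepoints, a per-participant intervention cap of
USD140. The evaluation questions are the standard care-continuum ones: did
engagement in care, retention in care and viral suppression change over the
program year, which baseline characteristics correlate with the 12-month
outcomes, and what did the program cost per quality-adjusted life year
(QALY) saved?

Because the underlying participant-level study data are not publicly
available, the package pairs every analysis stage with a seeded synthetic
cohort generator, so that the whole pipeline is testable end to end and
statistical properties (estimator calibration, type-I error, classification
invariants) can be verified by simulation. The one component checked
against published numbers cell by cell is the economic chain, whose inputs
(per-clinic cost components, enrolment counts, net suppression counts) are
printed in the source tables and shipped with the package
(`published_cost_inputs()`).

## Outcome definitions and windowing conventions

All three outcomes derive from dated viral-load tests:

* **Engagement**: at least one test in the reporting window.
* **Retention**: at least two tests at least 90 days apart in that window.
* **Suppression**: the most recent test within ±1 month of the reporting
  date reads below 200 copies/mL (strict inequality).

Conventions the package fixes (they are needed for testable arithmetic and
are exposed in `cascade_config()`):

* A "month" is 30 days everywhere; "12 months (±1 month)" is a 390-day
  forward window, "±1 month" a ±30-day reporting window.
* Window endpoints are inclusive.
* Baseline (t0) engagement and retention use the 12 months *before*
  enrollment; baseline suppression uses the enrollment-day test.
* The enrollment-day test is excluded from engagement/retention at every
  timepoint, not just baseline. The study design guarantees an
  enrollment-day test for everyone, so counting it would make follow-up
  engagement identically 100%; excluding it makes the outcome measure
  routine care rather than a study procedure.
* The 6-month timepoint uses the elapsed window (0, 210] days; the
  12-month timepoint (0, 390]. The windows nest, so engagement cannot fall
  between t1 and t2 by construction.
* Participants with no test in a window count as *not* achieving the
  outcome, with all enrolled participants in the denominator
  (missing-as-false). This is the only convention consistent with
  reporting outcome proportions of the full cohort, and it implies that
  declining suppression proportions can reflect missed labs as much as
  virologic rebound. A `complete_case` switch restricts the denominator to
  participants with at least one in-window test, without asserting that
  either convention matches any particular published analysis.

## Eligibility screening

Eligibility requires confirmed HIV diagnosis, local residence with no plans
to move, age ≥ 18, ability to take part in English, no concurrent-study or
institutionalization exclusion, and at least one criterion from:

* **Category A** — not in care for 8+ months (no viral-load test in 240
  days); or two *consecutive* detectable (≥200 copies/mL) results at least
  90 days apart, consecutive meaning adjacent in date order with no
  intervening test; or 2+ missed visits in the last six months.
* **Category B** — newly diagnosed (3–12 months before screening) with no
  test since diagnosis; or at least one self-reported risk factor for
  falling out of care (unstable housing, 3+ months unemployment,
  incarceration history, recent behavioral-health condition, the last two
  limited to a 12-month look-back).

When both categories hold, Category A takes precedence (it is the primary
stratum, with a protocol quota of ≥80% that the realized sample did not
reach; the generator defaults to the realized 58%/42% split and offers the
quota as a switch). The screening predicates are verified against an
independently written clause-by-clause evaluator on 1,000 random records.

## The synthetic cohort generator

`generate_cohort()` draws each participant from an independent substream of
one master seed, so cohorts are bit-reproducible and edits are local. It
emulates:

* **Demographics**: categorical marginals are count-weighted probabilities
  from the observed baseline composition of the emulated cohort
  (e.g. 89.2% Black/African American, 53.2% male, 42.6% unemployed);
  age is normal (42.4, SD 12.2) truncated at 18.
* **Lab-visit process**: window-level engagement indicators with default
  probabilities 0.70 / 0.85 / 0.93 at t0/t1/t2; engaged participants
  complete the ±1-month reporting lab with probability 0.95 and accrue
  additional routine visits as a Poisson count whose rate is
  `visit_rate_base` (1.0/year) times `incentive_visit_boost` (1.5)
  post-enrollment. Visit counts are drawn by evaluating the Poisson
  quantile function at a shared uniform draw, which makes every
  participant's test count pathwise monotone in the incentive boost — the
  property the incentive-effect tests check.
* **Viral loads**: suppressed tests read 50 copies/mL and detectable ones
  10,000 (only the 200 threshold matters); per-visit suppression
  probabilities default to 0.62 / 0.58 / 0.385, which combined with
  attendance imply marginal suppression near 62% / 47% / 34% under
  missing-as-false.
* **Surveys**: item-level acceptability (0–4, fourth item administered
  reverse-keyed), AUDIT-C, PHQ-9, CASE (3–16) and stigma (1–5) responses
  with per-instrument missingness rates matched to the emulated cohort's
  complete-case counts.
* **Missingness by non-attendance**: a non-engaged window simply has no
  tests; nothing is imputed.

What the generator does *not* emulate: viral-load kinetics or ART
pharmacology, transmission networks, within-site correlation beyond the
site label, informative (outcome-dependent) missingness, and secular or
pandemic-era disruptions to lab scheduling. Passing simulation tests
therefore show that the pipeline measures what it defines, under clean
at-random non-attendance — not that the generator's world matches any real
clinic population. Baseline retention (~0.42 expected with the default
rates) and follow-up retention are *emergent* from the visit process, not
calibrated targets; only engagement, suppression and the demographic
marginals are calibrated.

## Regression models

The time-trend model is a pooled logistic regression of each binary outcome
on time coded 0, 1, 2, with standard errors robust to within-participant
clustering (`sandwich::vcovCL`), and model-implied probabilities reported
at each time value (with time the only regressor, the average marginal
prediction equals the plug-in prediction). The published account of the
emulated study does not state whether its longitudinal model used random
effects or a working-correlation structure, and its printed slope
coefficients are not recoverable from its printed marginal proportions
under a pooled logit — so exact coefficient replication is out of scope by
design, a random-intercept variant (`lme4::glmer`) is provided as an
option, and verification is property-based instead: equivalence with a
directly maximized likelihood on small datasets (to 1e-6), 95% CI coverage
over 200 replicates with planted effects, and ~5% type-I error under a
flat-trend null.

The correlates analysis regresses each 12-month outcome on a benchmark set
(baseline value of the outcome, age, race/ethnicity, gender, relationship,
employment, housing, insurance, site, enrollment category; references Site
A, White, Female, Category B), then adds one incomplete covariate at a time
with the benchmark set as controls, reporting only the added term on its
complete-case subset. Factor levels that perfectly determine the outcome
(e.g. a site where nobody achieved suppression) are dropped and recorded,
as are covariates constant in the analysis subset. No multiple-testing
adjustment is applied, matching the evaluation design this package
implements.

## Incentive ledger

Ledger arithmetic is integer cents, so the audit identities are exact: the
per-participant intervention total can never exceed 14,000 cents, each
suppression incentive is issued at most once, and the number of lab
incentives distributed equals the sum over k of the number of participants
who received at least k of them. Incentives earned but pending at study
close count as distributed (a flag preserves the distinction). Survey
compensation (USD50 baseline / USD15 follow-up) is tracked outside the
intervention cap.

## Economic analysis

For each clinic, with C the societal-perspective cost (client + staff +
materials; the payor perspective excludes client-borne costs, and
evaluation costs are excluded entirely):

* infections averted `A = net_suppressed × 0.061` (annual transmission
  rate), reported to 2 decimals;
* QALYs `Q1 = 0.039 × net_suppressed`, `Q2 = 5.83 × A`, `Q = Q1 + Q2`;
* cost-utility ratio `R = (C − A·T)/(A·Q)` with `T = USD382,954` the
  lifetime treatment cost; `R < 0` means the program is dominant
  (cost-saving) and tables print the magnitude;
* thresholds `C/T` (transmissions to avert to be cost-saving) and `C/W`
  (QALYs to save to be cost-effective, `W = USD195,838.58`), plus the
  combined form `C/(T + Q·W)` evaluated with Q = 5.83 QALYs per averted
  transmission, since that formula is stated per transmission averted.

Two numeric conventions are forced by the printed worked examples and are
deliberate: **A and Q enter the ratio after rounding to 2 decimals** (the
only convention that reproduces the printed ratios to the cent), and
reported quantities round **half away from zero** (0.366 → 0.37), not
banker's rounding. Monetary aggregation is exact to the cent. The
`net_suppressed` person-years proxy is the net count of participants who
became suppressed during the program. Regional cost indexing is an identity
pass-through hook (no method is specified for it). Of the shipped
published inputs, two clinics' materials components are back-derived from
their printed totals (one component cell is unprinted, one printed
component set under-sums its printed, payor-consistent total); this is
documented in `?published_cost_inputs`.

## Problem sizes and numerical choices

The test suite and analysis scripts use cohorts of 120–1,000 participants
(781 — the emulated study's analytic n — for calibration checks), 200–1,000
random streams for oracle-equivalence properties, and 200 replicates for
coverage and type-I simulations; these sizes give 3-sigma binomial bounds
tight enough to detect miscalibration of a few percentage points while
keeping a full run in minutes on one core. Logistic fits use `stats::glm`
(IRLS); the independent test oracle maximizes the explicit log-likelihood
with BFGS to `reltol 1e-14` and the two agree to 1e-6 on small data.
Degenerate inputs error early and descriptively: empty cohorts, duplicate
status records, unsorted ledgers and lab histories, single-valued time,
all-missing covariates, zero denominators, and undefined cost-utility
ratios (A or Q zero).

## Known limitations

* The generator's independence assumptions (across participants and across
  windows) understate the serial correlation of real care behaviour;
  cluster-robust inference is therefore exercised under mild, not realistic,
  clustering.
* Published regression coefficients from the emulated study cannot be
  replicated without its data; only structural and statistical properties
  are verified.
* The suppression decline the missing-as-false convention produces is
  observationally confounded with lab non-attendance; the package reports
  the convention rather than resolving the ambiguity.
* Cost inputs are annual snapshots; no discounting, probabilistic
  sensitivity analysis, or budget-impact projection is implemented.
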