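#!/usr/bin/env Rscript
# Stage 4 — conditional-incentive accounting.
#
# Accrues the incentive ledger from the lab streams and cascade output:
# USD10 per post-enrollment lab (max 4), USD50 per suppression timepoint,
# USD140 intervention cap per participant; survey compensation tracked
# separately. Audits the at-least-k identity (total lab incentives = sum of
# the at-least-k participant counts).

library(cascadecea)

participants <- read_participants("results/participants.csv")
lab_tests <- read_lab_tests("results/lab_tests.csv")
statuses <- cascade_statuses(participants, lab_tests)

ledger <- build_ledger(participants, lab_tests, statuses)
out <- ledger
out$amount_usd <- out$amount_cents / 100
write_table(out[c("participant_id", "event_type", "date", "amount_usd")],
            "results/incentive_events.csv", money_cols = "amount_usd")

s <- ledger_summary(ledger)
cat("lab incentives: received at least k =", paste(s$at_least_k, collapse = ", "), "\n")
cat(sprintf("total lab incentives distributed: %d (identity check: %s)\n",
            s$total_lab_incentives,
            identical(s$total_lab_incentives, sum(ledger$event_type == "LAB"))))
cat(sprintf("suppression incentives: %d at 6 months, %d at 12 months\n",
            s$suppression_6m, s$suppression_12m))
cat(sprintf("USD distributed by type (LAB, S6, S12, SURVEY_B, SURVEY_F): %s\n",
            paste(sprintf("%.2f", s$total_usd_by_type), collapse = ", ")))
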