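#!/usr/bin/env Rscript
# Stage 2 — eligibility screening.
#
# Applies the gating criteria and the Category A / Category B rules to every
# simulated participant's history and reports the eligible share and the
# A/B split (the realized study split was 58%/42%).

library(cascadecea)

participants <- read_participants("results/participants.csv")
lab_tests <- read_lab_tests("results/lab_tests.csv")

report <- screen_cohort(participants, lab_tests)
write_table(report, "results/screening.csv")

cat(sprintf("eligible: %d of %d (%.1f%%)\n", sum(report$eligible), nrow(report),
            100 * mean(report$eligible)))
tab <- table(report$category)
for (k in names(tab)) cat(sprintf("  category %s: %d\n", k, tab[[k]]))
cat("most common qualifying rules:\n")
rules <- sort(table(unlist(strsplit(report$reasons[report$eligible], ";"))), decreasing = TRUE)
for (k in names(rules)) cat(sprintf("  %s: %d\n", k, rules[[k]]))
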