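#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs.
#
# Generates the synthetic stand-ins for the two historical data streams at
# the declared cohort shape: 102 autopsy records (ages < 25, deaths 0-117
# months post-diagnosis, exactly 60 recent-onset patients under age 20) and
# three C-peptide follow-up studies with N = 769, 24 and 41 participants.
# The generating model uses the fixture curves with alpha = 499.

library(ebcm)

seed <- 42
dir.create("results", showWarnings = FALSE)

model <- default_model(alpha = 499)
cohort <- generate_autopsy_cohort(cohort_config(seed = seed), model)
aggregates <- generate_cpeptide_aggregates(study_config(seed = seed + 500),
                                           model)

write_autopsy_csv(cohort, "results/autopsy.csv")
write_cpeptide_csv(aggregates, "results/cpeptide.csv")
write_model_json(model, "results/model.json")

message(sprintf(
  "Simulated %d autopsy records (%d recent-onset under age 20; deaths %.1f-%.1f months).",
  nrow(cohort), sum(cohort$recent_onset),
  min(cohort$time_since_diagnosis), max(cohort$time_since_diagnosis)))
message(sprintf(
  "Simulated %d C-peptide timepoints across studies of N = %s.",
  nrow(aggregates), paste(unique(aggregates$n), collapse = ", ")))
message("Wrote results/autopsy.csv, results/cpeptide.csv, results/model.json")
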