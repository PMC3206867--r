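#!/usr/bin/env Rscript
# Stage 5 — compile the run report.
#
# Collects the stage outputs into a single report.json stamped with the
# seed and package version. (The same end-to-end chain is available in one
# call as ebcm::run_pipeline().)

library(ebcm)

alpha <- jsonlite::read_json("results/alpha_estimate.json",
                             simplifyVector = TRUE)
posterior <- jsonlite::read_json("results/posterior.json",
                                 simplifyVector = TRUE)
cohort <- read_autopsy_csv("results/autopsy.csv")
pairs <- read.csv("results/pairs.csv")

report <- list(
  seed = posterior$seed,
  package_version = as.character(packageVersion("ebcm")),
  n_records = nrow(cohort),
  n_recent_onset_under20 = sum(cohort$time_since_diagnosis <= 0.75 &
                                 cohort$age < 20),
  alpha = alpha[c("alpha", "ci_low", "ci_high", "n_used", "method")],
  n_pairs = nrow(pairs),
  p_slope_positive = posterior$p_slope_positive,
  significant = posterior$significant,
  psrf = posterior$psrf,
  acceptance_fraction = posterior$acceptance_fraction)

jsonlite::write_json(report, "results/report.json", auto_unbox = TRUE,
                     digits = NA)
message(sprintf(
  "Report: alpha = %.1f (CI %.1f-%.1f), P(slope>0) = %.4f, significant = %s.",
  alpha$alpha, alpha$ci_low, alpha$ci_high,
  posterior$p_slope_positive, posterior$significant))
message("Wrote results/report.json")
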