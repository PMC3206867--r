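#!/usr/bin/env Rscript
# Stage 2 — estimate the insulin-demand parameter.
#
# Restricts the autopsy records to the recent-onset window (death within
# three weeks of diagnosis, age under 20) where predicted and observed
# excess beta cell mass should agree, and fits
# observed_ebcm = 1 - alpha * W(age)/BCM(age) by least squares. Also fits
# the descriptive linear trendline of observed EBCM on age for comparison.

library(ebcm)

model <- default_model(alpha = read_model_json("results/model.json")$alpha)
cohort <- read_autopsy_csv("results/autopsy.csv")

recent <- recent_onset_filter(cohort, cutoff = 0.75)
est <- fit_alpha(recent, model = model, method = "wls", age_max = 20)
trend <- linear_trendline(recent[recent$age < 20, ])

message(sprintf(
  "alpha = %.1f BCM-units/kg (95%% CI %.1f-%.1f) from %d recent-onset records.",
  est$alpha_hat, est$ci_low, est$ci_high, est$n_used))
message(sprintf(
  "Observed EBCM falls %.3f per year of age (linear trendline), i.e. the tolerable reduction shrinks with age.",
  -trend$slope))

jsonlite::write_json(
  list(alpha = est$alpha_hat, ci_low = est$ci_low, ci_high = est$ci_high,
       se = est$se, n_used = est$n_used, method = est$method,
       trendline = list(slope = trend$slope, intercept = trend$intercept)),
  "results/alpha_estimate.json", auto_unbox = TRUE, digits = NA)
message("Wrote results/alpha_estimate.json")
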