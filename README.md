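# ebcm — age-corrected excess beta cell mass and plasma C-peptide

`ebcm` implements a physiology-based inference pipeline for the natural
history of type 1 diabetes. Instead of assuming that clinical onset
requires the destruction of a fixed 80–95% of a person's beta cells, it
models onset as a dynamic imbalance between insulin demand, which grows
with body weight, and beta cell mass, which follows its own growth
trajectory. The package is aimed at quantitative biologists and
biostatisticians studying beta cell dynamics post-onset.

## The model

Body weight `W(a)` and total beta cell mass `BCM(a)` are interpolated
over age with natural cubic splines (the mass curve is the product of the
beta-cell-density and pancreas-volume splines). A steady-state insulin
balance gives the minimum mass compatible with euglycemia and the
normalized excess:

    BCM_min(a) = alpha * W(a)
    EBCM(a)    = 1 - alpha * W(a) / BCM(a)
    C_I        = q_max * rho * BCM / (k_clr * W(a))    (fasting steady state)

`EBCM(a)` is the fraction of beta cell mass that can be lost before
hyperglycemia — equal, in autopsy material, to the fraction of
insulin-deficient islets. The lumped demand parameter `alpha`
(BCM-units/kg) is fitted from recent-onset autopsy records (death within
three weeks of diagnosis, age < 20). The fitted model then predicts EBCM
for the full cohort; the predicted-minus-observed residuals, smoothed
with a nine-point moving average over time since diagnosis, are paired
with aggregate plasma C-peptide series and the association is tested with
a sample-size-weighted empirical-Bayes linear regression sampled by
adaptive random-walk Metropolis MCMC (3 chains, Gelman–Rubin convergence,
acceptance tuned to 0.4, 100,000 kept steps per chain). The headline
statistic is `P(slope > 0)`; values above 0.95 are read as significant.

Because the historical patient-level datasets are not redistributable,
the package ships seeded synthetic generators that reproduce the declared
cohort structure (102 autopsy records with 60 recent-onset patients under
age 20; three C-peptide studies of N = 769, 24 and 41) so the entire
pipeline runs from nothing.

## Worked example

The `analysis/` directory holds the staged workflow
(`01_simulate.R` … `05_report.R`, writing tables under `results/`); the
same chain is available in one call:

```r
library(ebcm)
report <- run_pipeline("results_demo", seed = 42)
```

which logs:

```
[ebcm] simulated 102 autopsy records
[ebcm] simulated 13 C-peptide timepoints
[ebcm] alpha = 517.7 (95% CI 497.7-537.7) from 60 recent-onset records
[ebcm] 94 moving-average windows over [0.005914, 99.68] months
[ebcm] 13 paired observations
[ebcm] P(slope > 0) = 1.0000 (PSRF 1.000/1.000)
```

Reading the numbers: the cohort was simulated with true
`alpha = 499` BCM-units/kg and refitted at 517.7 (within 4%, interval
covering the truth) from the 60 recent-onset records; the 102 residuals
give 94 nine-point windows; 13 study timepoints fall inside the smoothed
span; and the weighted MCMC regression of C-peptide on the smoothed
residual finds a positive slope with posterior probability ≈ 1 — plasma
C-peptide tracks the age-corrected residual beta cell mass, so it can
serve as a surrogate for beta cell mass, not only function. At the
default demand parameter the model predicts that a 20-year-old tolerates
only a ~40% mass reduction before onset (EBCM(20) = 1 − 499/829 ≈ 0.40)
versus ~85% in infancy.

See `vignettes/ebcm-methods.Rmd` for the model assumptions, numerical
choices and what the synthetic cohorts do and do not emulate.

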