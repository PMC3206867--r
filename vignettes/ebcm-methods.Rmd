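---
title: "Age-corrected excess beta cell mass: model, inference and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-corrected excess beta cell mass: model, inference and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physiological model

Clinical onset of type 1 diabetes is commonly attributed to the loss of a
fixed large fraction (80–95%) of a person's beta cells. The alternative
this package implements treats onset as a *dynamic imbalance*: insulin
demand grows with body size while beta cell mass follows its own growth
trajectory, so the tolerable loss depends on age.

The whole-body insulin amount $N$ obeys a balance between a source
proportional to beta cell mass and a clearance sink proportional to plasma
concentration times body volume:

$$\frac{dN}{dt} = q_{max}\,BCM - k_{clr}\,C_I\,\frac{W(a)}{\rho},$$

with $q_{max}$ the maximum insulin release per unit beta cell mass,
$k_{clr}$ the clearance rate constant, $W(a)$ body weight at age $a$, and
$\rho$ body density. Every quantity used downstream comes from the fasting
steady state ($dN/dt = 0$), so the package exposes the right-hand side
(`insulin_balance_rhs()`) for completeness but never integrates it.
At steady state,

$$C_I = \frac{q_{max}\,\rho\,BCM}{k_{clr}\,W(a)},$$

and requiring $C_I$ to reach the fasting set-point defines the *minimum*
beta cell mass compatible with euglycemia,

$$BCM_{min}(a) = \alpha\,W(a), \qquad
  \alpha = \frac{k_{clr}\,C_{I,fast}}{\rho\,q_{max}}.$$

Decomposing the total mass as $BCM(a) = BCM_{min}(a) + BCM_{excess}(a)$
gives the normalized excess beta cell mass

$$EBCM(a) = 1 - \frac{\alpha\,W(a)}{BCM(a)},$$

the fraction of beta cell mass that can be lost before hyperglycemia. In
autopsy material it corresponds to the fraction of insulin-deficient
islets. Only $\alpha$ is identifiable from such data; $q_{max}$, $k_{clr}$,
$\rho$ and the C-peptide proportionality $\gamma$ default to 1 and are
carried solely for dimensional bookkeeping.

Predictions are *not* clamped to $[0,1]$: a negative EBCM means demand
exceeds total mass and is meaningful. Observed islet fractions, being
proportions, are validated into $[0,1]$ at ingestion.

## Age curves

`fit_cubic_spline()` interpolates tabulated age trends with natural cubic
splines (zero second derivative at both ends). Natural boundaries are the
conventional choice for sparse biological trend tables; the implementation
delegates to `stats::splinefun(method = "natural")` and is verified in the
tests against the hand-solved tridiagonal system for a three-knot case.
Body weight $W(a)$ is the pointwise average of male and female
weight-for-age tables, resampled onto the union age grid
(`average_growth_chart()`). Total mass $BCM(a)$ is the product of the beta
cell density and pancreas volume splines; `bcm_total_curve()` samples the
product on a 200-point uniform grid *plus* the union of the input knots
(so the product is exact at shared knots) and re-splines, keeping a single
curve type downstream. The re-splined product stays within 0.5% of the
pointwise product at that grid density.

Outside its knot range a curve is **clamped** to the boundary value. The
source tables end near ages 20–25 and cubic extrapolation of growth
tables diverges; clamping is the conservative rule and is applied
uniformly.

The packaged knot tables under `inst/extdata/` are synthetic,
representative stand-ins (the original growth-chart and histology tables
are not redistributed). They are scaled so that
$BCM(20)/W(20) = 829$ BCM-units/kg: at the published point estimate
$\alpha = 499$ this reproduces the reported age profile — roughly 85%
tolerable loss in the youngest patients falling to about 40%
($1 - 499/829 = 0.398$) by age 20.

## Estimating the demand parameter

At onset the predicted and observed EBCM should coincide, so $\alpha$ is
fit on the *recent-onset* subset: death within three weeks of diagnosis
(0.75 months at a 28-day-month convention; configurable) and age under 20,
matching the 60-record cohort the published fit used. The default
estimator is least squares in the single parameter,

$$\hat\alpha = \frac{\sum_i w_i r_i (1 - y_i)}{\sum_i w_i r_i^2},
  \qquad r_i = W(a_i)/BCM(a_i),$$

with a t-based 95% interval from the curvature of the residual sum of
squares (df $n-1$). Records are unweighted by default (whether the
original fit weighted by islet counts is not stated). An MCMC alternative
(`method = "mcmc"`, flat prior on $\alpha > 0$, same profiled-variance
Gaussian likelihood) is provided and agrees with the least-squares fit
within the interval width on well-conditioned data. Observed fractions of
exactly 0 or 1 are retained — the likelihood is Gaussian, not binomial, so
no continuity correction is needed.

## Residual trajectory and C-peptide alignment

For the full cohort, `residual_series()` computes
$\Delta EBCM_i = \widehat{EBCM}(a_i) - \text{observed}_i$, sorted by time
since diagnosis (ties broken by patient id). Positive residuals mean fewer
insulin-deficient islets than the age-corrected expectation — recovery of
mass after onset; negative residuals mean further decline.

`moving_average()` smooths the ordered series with **full centered
9-point windows** (window over record index, not a fixed time width):
$n$ points give $n - 9 + 1$ windows, each centered at the time of its
middle record, reporting the window mean and sample SD (denominator 8).
Partial edge windows are dropped — the smoothing is described as centered
and nothing is stated about edges, and shrinking windows would bias the
ends. Time is in months throughout (weeks convert at 4.345 weeks/month).

`align_with_cpeptide()` reads the smoothed residual at each C-peptide
timepoint by linear interpolation between window centers
(nearest-center lookup is available as an option; how the original
matching was done is not stated, and linear interpolation is the milder
assumption). Timepoints outside the span of window centers cannot be
matched and are dropped with a warning. The moving SD is carried along as
`x_sd` but, as in the source analysis, is not modelled
(no errors-in-variables correction).

## Weighted empirical-Bayes regression by MCMC

The association between C-peptide means $y_i$ and smoothed residuals
$x_i$ is tested with a Bayesian linear regression weighted by study sample
size: $y_i \sim N(a + b x_i,\ \sigma^2 / w_i)$ with
$w_i = n_i / \sum n$. Rather than sampling $\sigma^2$, each likelihood
evaluation plugs in its conditional maximum
$\hat\sigma^2 = \sum_i w_i r_i^2 / n$ (empirical-Bayes plug-in, floored at
$10^{-12}$ for exactly collinear data). Up to this profiling the
likelihood ranks parameters exactly like weighted least squares, and under
a flat improper prior on $(b, a)$ the implied slope posterior is a
$t_{n-2}$ centered at the WLS estimate — which the tests exploit as an
analytic oracle. The "unbiased Gaussian prior" of the source description
refers to the proposal distribution, not the parameter prior, and is
treated as such. Whether the original weights were raw or normalized N is
unstated; normalization is immaterial because the scale is absorbed by
$\sigma^2$.

Sampling is random-walk Metropolis with componentwise Gaussian proposals:

* **Initialization.** Chains start overdispersed at the WLS estimate plus
  $\{-1, 0, +1\} \times 4$ standard errors.
* **Adaptation.** Per 250-step batch the proposal scale is multiplied by
  $\exp(0.7\,(acc - 0.4))$ until two consecutive batches land within
  $\pm 0.05$ of the 0.4 target; a verification stage then re-measures
  acceptance over 2000-step batches and freezes the scale only when a
  batch lands within $\pm 0.03$ (batch noise sd ≈ 0.011, so the long-run
  post-adaptation fraction stays inside $0.40 \pm 0.05$). Adaptation
  samples are discarded; the scale is frozen afterwards, keeping the
  production chains Markovian.
* **Convergence.** The chains run in doubling windows (250, 500, 1000, …)
  and the Gelman–Rubin PSRF
  $\sqrt{((n-1)/n\,W + B/n)/W}$ is computed per parameter on the latest
  window; burn-in ends at the first window with both PSRFs below 1.1 (the
  conventional cutoff; none is stated in the source). Convergence is
  assessed per parameter with a both-below-threshold rule. Failure within
  the 32,000-step pilot budget raises an error carrying the last PSRFs.
* **Production.** 100,000 post-convergence steps per chain (default; 3
  chains), over which the acceptance fractions and reported PSRF are
  measured. Proposals tying the current log-likelihood are accepted
  (standard log-uniform comparison). `P(slope > 0)` is the fraction of
  pooled slope samples above zero, with significance declared above 0.95.
* **Reproducibility.** All stochastic stages derive their streams from the
  master seed (per-chain blocks of 1000 with fixed phase offsets), so a
  rerun with the same seed is bit-identical.

## What the synthetic generators emulate

No patient-level data ship with the package; seeded generators reproduce
the *statistical shape* the analysis assumes.

`generate_autopsy_cohort()` draws 102 records with ages uniform on
0.5–25 years and deaths uniform on 0–117 months, forcing exactly 60
records into the (age < 20, ≤ 3 weeks) cell by quota sampling (the true
age/time joint distribution is unpublished; uniform is a declared
stand-in). Observed EBCM is
$\mathrm{clamp}_{[0,1]}(EBCM(a) - r(t) + \varepsilon)$ with
$\varepsilon \sim N(0, 0.08)$ and the recovery kernel

$$r(t) = A\,\frac{t}{t_{peak}}\,e^{1 - t/t_{peak}} - d\,\max(0, t - t_{peak}),$$

a unimodal rise peaking at $t_{peak} = 2.3$ months (≈ 10 weeks) followed
by a linear decline — the simplest shape matching the described
rise-then-decline trajectory.

**Choice of the kernel amplitudes.** The defaults are $A = 0.005$ and
$d = 0.005$/month, chosen a priori from two constraints. First, the
demand-parameter fit presumes predicted ≈ observed inside the three-week
window; the mean kernel value in that window is $0.377 A$ and propagates
into a bias of roughly $1300 \times 0.377 A$ on $\hat\alpha$, so a
recovery that is *slight* relative to the islet-count noise (sd 0.08)
keeps the fit unbiased — $A = 0.005$ contributes ≈ 0.5% to a true value
of 499. Second, the late decline, not the early rise, carries the
long-run trend: $d = 0.005$/month accumulates to ≈ −0.57 over the
117-month span, dominating the smoothed trajectory and the C-peptide
correlation. Larger amplitudes remain available through
`cohort_config()`.

`generate_cpeptide_aggregates()` mirrors the three pooled follow-up
studies (N = 769 over 24 months with random sampling; N = 24 and N = 41
over 12 months, fasting). Study means follow the same latent kernel:
$\mu(t) = \gamma\,\max(0,\ C_{set}\,(1 - \delta_0 + r(t)))$ with baseline
deficit $\delta_0 = 0.5$ and $\gamma = 0.0012$ nmol/L per set-point unit,
putting post-onset means near 0.3 nmol/L; the study-level SE is
$0.3/\sqrt{n}$ nmol/L. Autoantibody strata and sampling condition are
carried as labels only, and random (non-fasting) values are pooled
unadjusted, as in the source analysis.

What passing tests on these cohorts do **not** show: recovery of the
printed confidence interval (458–605) or the exact age-specific
reductions, which depend on the unpublished digitized curves and
patient-level records; robustness to non-uniform age/time distributions;
or behaviour under assay artefacts (censoring at detection limits,
between-study calibration shifts) that the generators do not emulate.

## Problem sizes

The test suite runs the full protocol (3 × 100,000 kept steps) for the
headline posterior-probability and acceptance-fraction checks, and reduced
chains (4,000–30,000 kept steps) for oracle-agreement, calibration (50
seeded null replicates at 10,000 steps) and reproducibility properties —
sizes at which the Monte-Carlo error is well below every asserted
tolerance. Interval coverage of the demand parameter is checked over a
$\{300, 499, 700\}$ grid with 100 seeded replicates each.

## Known limitations

* The model is a steady-state balance: no glucose dynamics, secretion
  pulsatility, or functional compensation kinetics.
* EBCM equates histological insulin-deficiency with lost functional mass;
  partially degranulated islets blur that equivalence.
* The regression treats smoothed residuals as fixed covariates; the
  moving SD is reported but not propagated.
* BCM units are abstract. Only the ratio $\alpha W / BCM$ is observable,
  so $\alpha$ and the BCM curve rescale jointly (the fit is exactly
  equivariant, as the tests assert).
* Clamped extrapolation flattens the weight curve above age 20, so
  predictions for the 20–25-year records inherit the age-20 set-point.
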