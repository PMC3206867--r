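make_records <- function(ages, times, ebcm, ids = NULL) {
  autopsy_records(data.frame(
    patient_id = ids %||% sprintf("P%02d", seq_along(ages)),
    study = "t", age = ages, time_since_diagnosis = times,
    observed_ebcm = ebcm, stringsAsFactors = FALSE))
}

test_that("recent-onset filter keeps the three-week window in order", {
  rec <- make_records(ages = c(5, 8, 3), times = c(0.5, 2, 0.7),
                      ebcm = c(0.8, 0.7, 0.9))
  kept <- recent_onset_filter(rec, cutoff = 0.75)
  expect_equal(kept$patient_id, c("P01", "P03"))
  expect_equal(nrow(recent_onset_filter(rec, cutoff = 3)), 3)
  expect_error(recent_onset_filter(rec, cutoff = 0), "positive")
  expect_error(recent_onset_filter(rec, cutoff = -1), "positive")
})

test_that("default synthetic cohort yields 60 records under the combined filter", {
  rec <- generate_autopsy_cohort(cohort_config(seed = 11), fixture_model())
  sub <- recent_onset_filter(rec)
  expect_equal(sum(sub$age < 20), 60)
})

test_that("alpha is recovered exactly from noiseless records", {
  m <- fixture_model(alpha = 300)
  ages <- c(1, 3, 6, 9, 12, 15, 18)
  rec <- make_records(ages, times = rep(0.2, 7),
                      ebcm = excess_bcm(m, ages)$ebcm)
  est <- fit_alpha(rec, model = m)
  expect_equal(est$alpha_hat, 300, tolerance = 1e-6)
  expect_true(est$ci_low <= est$alpha_hat && est$alpha_hat <= est$ci_high)
})

test_that("degenerate designs are rejected", {
  m <- fixture_model()
  rec1 <- make_records(rep(10, 5), rep(0.2, 5), rep(0.5, 5))
  expect_error(fit_alpha(rec1, model = m), "single age")
  rec2 <- make_records(c(5, 10), c(0.2, 0.2), c(0.8, 0.6))
  expect_error(fit_alpha(rec2, model = m), "at least 3")
})

test_that("alpha is recovered within 5% at the published noise level", {
  m <- fixture_model()
  rec <- generate_autopsy_cohort(cohort_config(seed = 42), m)
  est <- fit_alpha(recent_onset_filter(rec), model = m)
  expect_equal(est$n_used, 60)
  expect_lt(abs(est$alpha_hat - 499) / 499, 0.05)
})

test_that("the 95% interval covers the generating alpha in >= 90% of replicates", {
  for (a0 in c(300, 499, 700)) {
    m <- fixture_model(alpha = a0)
    hits <- vapply(1:100, function(s) {
      rec <- generate_autopsy_cohort(cohort_config(seed = s), m)
      est <- fit_alpha(recent_onset_filter(rec), model = m)
      est$ci_low <= a0 && a0 <= est$ci_high
    }, logical(1))
    expect_gte(mean(hits), 0.90)
  }
})

test_that("fit is equivariant under rescaling of the BCM curve", {
  m <- fixture_model()
  rec <- generate_autopsy_cohort(cohort_config(seed = 3), m)
  sub <- recent_onset_filter(rec)
  est <- fit_alpha(sub, model = m)
  c0 <- 2.5
  kn <- m$bcm_curve$knots
  bcm2 <- fit_cubic_spline(age_knots(kn$ages, c0 * kn$values))
  est2 <- fit_alpha(sub, weight_curve = m$weight_curve, bcm_curve = bcm2)
  expect_equal(est2$alpha_hat, c0 * est$alpha_hat, tolerance = 1e-9)
  expect_equal(est2$ci_low, c0 * est$ci_low, tolerance = 1e-9)
})

test_that("estimator bias shrinks as the noise level falls", {
  m <- fixture_model()
  bias_at <- function(sd) {
    errs <- vapply(1:30, function(s) {
      cfg <- cohort_config(seed = s, ebcm_noise_sd = sd, A = 0, d = 0)
      est <- fit_alpha(recent_onset_filter(generate_autopsy_cohort(cfg, m)),
                       model = m)
      est$alpha_hat - 499
    }, numeric(1))
    abs(mean(errs))
  }
  b <- c(bias_at(0.16), bias_at(0.08), bias_at(0.02))
  expect_true(all(diff(b) < 0))
})

test_that("MCMC posterior for alpha agrees with the least-squares fit", {
  m <- fixture_model()
  rec <- recent_onset_filter(generate_autopsy_cohort(cohort_config(seed = 5), m))
  wls <- fit_alpha(rec, model = m, method = "wls")
  mc <- fit_alpha(rec, model = m, method = "mcmc",
                  config = mcmc_config(n_steps = 10000, seed = 2))
  width <- wls$ci_high - wls$ci_low
  expect_lt(abs(mc$alpha_hat - wls$alpha_hat), width)
  expect_equal(mc$ci_high - mc$ci_low, width, tolerance = 0.35)
})

test_that("linear trendline matches the normal-equations oracle", {
  rec <- make_records(c(0, 20), c(0.1, 0.1), c(0.8, 0.4))
  tl <- linear_trendline(rec)
  expect_equal(tl$slope, -0.02)
  expect_equal(tl$intercept, 0.8)

  recc <- make_records(c(2, 9, 14), rep(0.1, 3), rep(0.55, 3))
  expect_equal(linear_trendline(recc)$slope, 0)

  set.seed(8)
  ages <- runif(50, 1, 20)
  eb <- pmin(pmax(0.9 - 0.02 * ages + rnorm(50, 0, 0.1), 0), 1)
  tl2 <- linear_trendline(make_records(ages, rep(0.1, 50), eb))
  oracle <- ols_oracle(ages, eb)
  expect_equal(tl2$intercept, oracle[1], tolerance = 1e-10)
  expect_equal(tl2$slope, oracle[2], tolerance = 1e-10)

  expect_error(linear_trendline(make_records(rep(5, 4), rep(0.1, 4),
                                             rep(0.5, 4))), "distinct")
})
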