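test_that("recovery kernel rises to a unique maximum at t_peak", {
  t <- seq(0, 30, by = 0.01)
  r <- recovery_kernel(t, A = 0.1, t_peak = 2.3, d = 0.005)
  expect_equal(t[which.max(r)], 2.3, tolerance = 0.011)
  expect_equal(max(r), 0.1, tolerance = 1e-6)
  # strictly rising before the peak, strictly falling after
  expect_true(all(diff(r[t < 2.3]) > 0))
  expect_true(all(diff(r[t > 2.3]) < 0))
  expect_equal(recovery_kernel(0), 0)
})

test_that("synthetic cohort reproduces the declared cohort shape", {
  m <- fixture_model()
  rec <- generate_autopsy_cohort(cohort_config(seed = 7), m)
  expect_equal(nrow(rec), 102)
  expect_equal(sum(rec$age < 20 & rec$time_since_diagnosis <= 0.75), 60)
  expect_true(all(rec$age >= 0.5 & rec$age < 25))
  expect_true(all(rec$time_since_diagnosis >= 0 &
                    rec$time_since_diagnosis <= 117))
  expect_true(all(rec$observed_ebcm >= 0 & rec$observed_ebcm <= 1))
  expect_equal(sum(rec$recent_onset), 60)
})

test_that("cohort generation is deterministic given the seed", {
  m <- fixture_model()
  expect_identical(generate_autopsy_cohort(cohort_config(seed = 5), m),
                   generate_autopsy_cohort(cohort_config(seed = 5), m))
  r1 <- generate_autopsy_cohort(cohort_config(seed = 5), m)
  r2 <- generate_autopsy_cohort(cohort_config(seed = 6), m)
  expect_false(identical(r1$observed_ebcm, r2$observed_ebcm))
})

test_that("noiseless flat-kernel cohort equals the model prediction", {
  m <- fixture_model()
  cfg <- cohort_config(seed = 2, ebcm_noise_sd = 0, A = 0, d = 0)
  rec <- generate_autopsy_cohort(cfg, m)
  expect_equal(rec$observed_ebcm, excess_bcm(m, rec$age)$ebcm,
               tolerance = 1e-12)
})

test_that("infeasible recent-onset quota is rejected", {
  expect_error(cohort_config(n_patients = 50, n_recent_onset_under20 = 60),
               "quota")
})

test_that("synthetic C-peptide studies mirror the pooled study sizes", {
  m <- fixture_model()
  agg <- generate_cpeptide_aggregates(study_config(seed = 3), m)
  expect_setequal(unique(agg$n), c(769, 24, 41))
  expect_true(all(agg$time_since_diagnosis <= 24))
  expect_true(all(agg$mean >= 0))
  expect_identical(agg, generate_cpeptide_aggregates(study_config(seed = 3), m))

  # SE scales as 1/sqrt(n): quadrupling n halves the SE
  s1 <- study_config(studies = list(list(label = "a", n = 25,
                                         timepoints = c(3, 6),
                                         stratum = "mixed",
                                         sampling = "fasting")))
  s4 <- study_config(studies = list(list(label = "a", n = 100,
                                         timepoints = c(3, 6),
                                         stratum = "mixed",
                                         sampling = "fasting")))
  expect_equal(generate_cpeptide_aggregates(s1, m)$se,
               2 * generate_cpeptide_aggregates(s4, m)$se)
})

test_that("gamma = 0 is rejected and gamma scales the C-peptide means", {
  expect_error(study_config(gamma = 0), "gamma")
  m <- fixture_model()
  a1 <- generate_cpeptide_aggregates(study_config(seed = 4, gamma = 0.001,
                                                  cpep_noise_sd = 0), m)
  a2 <- generate_cpeptide_aggregates(study_config(seed = 4, gamma = 0.002,
                                                  cpep_noise_sd = 0), m)
  expect_equal(a2$mean, 2 * a1$mean)
})

test_that("regression pair generator honors its contract", {
  # zero noise: exactly collinear
  p0 <- generate_regression_pairs(0.3, -0.1, n = 12, noise_sd = 0, seed = 5)
  expect_equal(p0$y, 0.3 * p0$x - 0.1, tolerance = 1e-12)

  expect_identical(generate_regression_pairs(0.1, 0, n = 10, seed = 8),
                   generate_regression_pairs(0.1, 0, n = 10, seed = 8))

  # true slope 0: WLS estimate within 3 closed-form SEs of zero
  p <- generate_regression_pairs(0, 0.5, n = 200, noise_sd = 0.05, seed = 12)
  fit <- lm(y ~ x, data = p, weights = p$weight)
  s <- summary(fit)$coefficients["x", ]
  expect_lt(abs(s["Estimate"]), 3 * s["Std. Error"])

  expect_error(generate_regression_pairs(0, 0, n = 2), "n >= 3")
  expect_error(generate_regression_pairs(0, 0, n = 5, x_range = c(1, 1)),
               "non-degenerate")
  expect_error(generate_regression_pairs(0, 0, n = 5, noise_sd = -1),
               ">= 0")
})
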