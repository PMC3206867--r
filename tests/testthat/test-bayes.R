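test_that("regression data validates pairs and normalizes weights", {
  p <- generate_regression_pairs(0.1, 0, n = 10, seed = 1)
  d <- regression_data(p)
  expect_equal(sum(d$w), 1)
  expect_error(regression_data(p[1:2, ]), "at least 3")
  p$weight[1] <- -1
  expect_error(regression_data(p), "positive")
})

test_that("profiled log-likelihood is maximized at the weighted LS solution", {
  # exactly collinear points: the line itself maximizes the likelihood
  coll <- data.frame(x = c(0, 1, 2), y = c(1, 1.5, 2), weight = c(5, 1, 2))
  d <- regression_data(coll)
  ll0 <- log_likelihood(0.5, 1, d)
  for (eps in c(-0.1, 0.05, 0.2))
    expect_gt(ll0, log_likelihood(0.5 + eps, 1 - eps / 2, d))

  # equal weights: parameter ranking identical to the OLS residual sum
  set.seed(4)
  p <- data.frame(x = runif(15), y = rnorm(15), weight = 1)
  de <- regression_data(p)
  grid <- expand.grid(b = seq(-1, 1, by = 0.25), a = seq(-1, 1, by = 0.25))
  ll <- mapply(function(b, a) log_likelihood(b, a, de), grid$b, grid$a)
  rss <- mapply(function(b, a) sum((p$y - a - b * p$x)^2), grid$b, grid$a)
  expect_equal(order(ll), order(-rss))

  # argmax matches the weighted normal-equations oracle
  pw <- generate_regression_pairs(0.3, -0.2, n = 20, noise_sd = 0.1,
                                  weights = c(9, 1, 4, 16), seed = 6)
  dw <- regression_data(pw)
  opt <- optim(c(0, 0), function(th) -log_likelihood(th[1], th[2], dw),
               method = "BFGS", control = list(reltol = 1e-14))
  oracle <- ols_oracle(dw$x, dw$y, dw$w)
  expect_equal(opt$par[1], oracle[2], tolerance = 1e-6)
  expect_equal(opt$par[2], oracle[1], tolerance = 1e-6)
})

test_that("metropolis sampler recovers a known bivariate normal target", {
  ll <- function(th) -0.5 * sum(th^2)
  ch <- metropolis_chain(ll, init = c(0.5, -0.5), proposal_sd = c(1, 1),
                         config = mcmc_config(n_steps = 100000),
                         chain_seed = 99)
  expect_lt(max(abs(colMeans(ch$samples))), 0.05)
  expect_lt(max(abs(apply(ch$samples, 2, sd) - 1)), 0.05)
  expect_gt(ch$acceptance_fraction, 0.35)
  expect_lt(ch$acceptance_fraction, 0.45)
})

test_that("metropolis sampler validates its inputs", {
  ll <- function(th) -0.5 * sum(th^2)
  expect_error(metropolis_chain(ll, c(0, 0), proposal_sd = c(0, 1)),
               "positive")
  expect_error(metropolis_chain(function(th) NaN, c(0, 0), c(1, 1)),
               "finite")
})

test_that("Gelman-Rubin PSRF matches the formula oracle", {
  psrf_oracle <- function(mat) {
    # mat: steps x chains, straight from the between/within definition
    n <- nrow(mat)
    W <- mean(apply(mat, 2, var))
    B <- n * var(colMeans(mat))
    sqrt(((n - 1) / n * W + B / n) / W)
  }
  set.seed(31)
  n <- 10000
  same <- replicate(3, rnorm(n), simplify = FALSE)
  psrf <- gelman_rubin(same)
  expect_lt(psrf, 1.05)
  expect_equal(psrf, psrf_oracle(do.call(cbind, same)), tolerance = 1e-12)

  apart <- list(rnorm(1000, 0, 1), rnorm(1000, 10, 1))
  psrf2 <- gelman_rubin(apart)
  expect_gt(psrf2, 1.1)
  expect_equal(psrf2, psrf_oracle(do.call(cbind, apart)), tolerance = 1e-12)

  # duplicated chain: B = 0 gives the exact lower bound sqrt((n-1)/n)
  dup <- rnorm(500)
  expect_equal(gelman_rubin(list(dup, dup)), sqrt(499 / 500),
               tolerance = 1e-12)

  expect_error(gelman_rubin(list(rep(1, 100), rep(1, 100))), "degenerate")
  expect_error(gelman_rubin(list(rnorm(100))), "2 chains")
  expect_error(gelman_rubin(list(rnorm(100), rnorm(50))), "equal lengths")
})

test_that("posterior agrees with the weighted least-squares closed form", {
  for (s in c(2, 17)) {
    p <- generate_regression_pairs(0.15, 0.1, n = 25, noise_sd = 0.05,
                                   weights = c(20, 5, 1), seed = s)
    d <- regression_data(p)
    post <- run_regression(d, mcmc_config(n_steps = 10000, seed = s))
    oracle <- ols_oracle(d$x, d$y, d$w)
    expect_lt(abs(mean(post$slope_samples) - oracle[2]),
              3 * mcse_pooled(post$slope_samples))
    expect_lt(abs(mean(post$intercept_samples) - oracle[1]),
              3 * mcse_pooled(post$intercept_samples))
    expect_true(all(post$acceptance_fraction >= 0.35 &
                      post$acceptance_fraction <= 0.45))
    expect_true(all(post$psrf < post$config$psrf_threshold))
  }
})

test_that("posterior slope probability matches the analytic t oracle", {
  # flat prior + profiled variance => slope posterior is a t with n-2 df
  # centered at the WLS estimate, so P(slope > 0) = pt(bhat / se, n - 2)
  p <- generate_regression_pairs(0, 0.2, n = 20, noise_sd = 0.05, seed = 7)
  d <- regression_data(p)
  fit <- lm(y ~ x, data = data.frame(x = d$x, y = d$y), weights = d$w)
  tstat <- summary(fit)$coefficients["x", "t value"]
  p_oracle <- pt(tstat, df = 18)
  post <- run_regression(d, mcmc_config(n_steps = 30000, seed = 5))
  expect_equal(post$p_slope_positive, p_oracle, tolerance = 0.03)
})

test_that("seeded runs are reproducible and chains are distinct", {
  p <- generate_regression_pairs(0.1, 0, n = 15, noise_sd = 0.05, seed = 3)
  d <- regression_data(p)
  cfg <- mcmc_config(n_steps = 4000, seed = 11)
  post1 <- run_regression(d, cfg)
  post2 <- run_regression(d, cfg)
  expect_identical(posterior_summary(post1), posterior_summary(post2))
  # distinct chain seeds give distinct sample paths
  expect_false(identical(post1$slope_samples[1:100, 1],
                         post1$slope_samples[1:100, 2]))
  expect_false(identical(post1$slope_samples[1:100, 2],
                         post1$slope_samples[1:100, 3]))
})

test_that("slope and intercept are anti-correlated for positive mean x", {
  p <- generate_regression_pairs(0.2, 0.1, n = 20, x_range = c(0.1, 0.9),
                                 noise_sd = 0.05, seed = 9)
  post <- run_regression(regression_data(p),
                         mcmc_config(n_steps = 10000, seed = 4))
  expect_lt(post$slope_intercept_correlation, 0)
  expect_gte(post$slope_intercept_correlation, -1)
})

test_that("posterior summary reports intervals containing the WLS estimate", {
  p <- generate_regression_pairs(0.15, 0.05, n = 30, noise_sd = 0.03,
                                 seed = 13)
  d <- regression_data(p)
  post <- run_regression(d, mcmc_config(n_steps = 8000, seed = 8))
  summ <- posterior_summary(post)
  oracle <- ols_oracle(d$x, d$y, d$w)
  sl <- summ[summ$parameter == "slope", ]
  ic <- summ[summ$parameter == "intercept", ]
  expect_true(sl$ci_lower <= oracle[2] && oracle[2] <= sl$ci_upper)
  expect_true(ic$ci_lower <= oracle[1] && oracle[1] <= ic$ci_upper)
  expect_equal(attr(summ, "p_slope_positive"), post$p_slope_positive)
})
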