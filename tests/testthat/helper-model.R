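# Shared in-code fixtures: tiny curves and models built fresh per session.

`%||%` <- function(a, b) if (is.null(a)) b else a

const_curve <- function(value, ages = c(0, 10, 20)) {
  fit_cubic_spline(age_knots(ages, rep(value, length(ages))))
}

linear_curve <- function(slope, intercept = 0, ages = c(0, 5, 10, 15, 20)) {
  fit_cubic_spline(age_knots(ages, intercept + slope * ages))
}

# Model with constant weight W and constant total mass B: ebcm is
# age-independent, handy for arithmetic checks.
const_model <- function(alpha, W = 40, B = 100, ...) {
  physiology_model(const_curve(W), const_curve(B), alpha = alpha, ...)
}

# Cached package default model (fixture curves are read from inst/extdata).
fixture_model <- local({
  cache <- NULL
  function(alpha = 499) {
    if (is.null(cache)) cache <<- default_model()
    if (alpha == 499) cache
    else physiology_model(cache$weight_curve, cache$bcm_curve, alpha = alpha)
  }
})

# Hand-written normal-equations solver, kept independent of stats::lm for
# oracle comparisons: returns c(intercept, slope).
ols_oracle <- function(x, y, w = rep(1, length(x))) {
  X <- cbind(1, x)
  unname(solve(t(X) %*% (w * X), t(X) %*% (w * y))[, 1])
}

# Monte-Carlo standard error of the pooled posterior mean via batch means
# (20 batches per chain, robust to within-chain autocorrelation).
mcse_pooled <- function(samples, n_batches = 20) {
  n <- nrow(samples)
  idx <- rep(seq_len(n_batches), each = ceiling(n / n_batches))[seq_len(n)]
  bm <- as.vector(apply(samples, 2, function(v) tapply(v, idx, mean)))
  stats::sd(bm) / sqrt(length(bm))
}

# Weighted-regression dataset wrapper for engine tests.
pairs_data <- function(...) regression_data(generate_regression_pairs(...))
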