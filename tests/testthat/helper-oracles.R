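# Independent brute-force oracles used to cross-check the package's fitted
# statistics. Deliberately written from the explicit normal-equation /
# ANOVA-decomposition formulas, not via lm().

ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  sse <- sum((y - fitted)^2)
  syy <- sum((y - mean(y))^2)
  list(
    intercept = intercept, slope = slope,
    r2 = 1 - sse / syy, sse = sse, syy = syy,
    residual_se = sqrt(sse / (n - 2)),
    residuals = y - fitted, fitted = fitted, n = n
  )
}

# F statistic from the ANOVA decomposition SSR/(SSE/(n-2))
anova_f_oracle <- function(x, y) {
  o <- ols_oracle(x, y)
  ssr <- o$syy - o$sse
  ssr / (o$sse / (o$n - 2))
}

# random small regression instance
random_instance <- function() {
  n <- sample(4:10, 1)
  x <- sort(runif(n, 0, 2)) + seq_len(n) * 1e-3  # distinct x
  y <- runif(1, -2, 2) + runif(1, -3, 3) * x + rnorm(n, 0, runif(1, 0, 0.5))
  list(x = x, y = y)
}

# a small fast generator config for pipeline tests
small_config <- function(seed, noise_sd = 0.02, n_phi = NULL, replicates = 3) {
  generator_config(
    systems = default_systems(n_phi = n_phi),
    noise_sd = noise_sd, replicates = replicates, seed = seed
  )
}
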