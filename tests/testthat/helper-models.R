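## Shared model presets and small utilities for the test suite.

gauss1 <- function() kernel_spec("gaussian", 1)

## logistic preset: r = gamma = 1, F = 1 - m
logistic_dem <- function(theta, N, kernel = gauss1()) {
  demography("constant", "constant", "logistic_F",
             theta = theta, N = N, kernels = kernel)
}

## porous-medium preset: r = 1, gamma = m (capped), F = 1 - m
pme_dem <- function(theta, N, kernel = gauss1()) {
  demography(rate_fn("linear_gamma"), "constant", "logistic_F",
             theta = theta, N = N, kernels = kernel,
             m_min = 1 / (theta + 1))
}

## critical preset: r = gamma = 1, F = 0 (so mu_theta = 1 exactly)
critical_dem <- function(theta, N, kernel = gauss1()) {
  demography("constant", "constant", rate_fn("constant", c = 0),
             theta = theta, N = N, kernels = kernel)
}

## empirical-vs-analytic CDF sup distance on a grid
ks_distance <- function(sample, x, density) {
  dxg <- diff(x[1:2])
  cdf <- cumsum(density) * dxg
  max(abs(stats::ecdf(sample)(x) - cdf))
}

## commensurate periodic grid
periodic_grid <- function(n, dx) (0:(n - 1)) * dx
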