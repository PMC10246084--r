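test_that("wave-frame coefficients reproduce the printed generators", {
  kpp <- lineage_coeffs(wave_frame_model("fisher_kpp"))
  expect_equal(kpp$drift_fn(-12), 2, tolerance = 0.01)   # bulk: drift -> 2
  expect_lt(abs(kpp$drift_fn(10)), 0.2)                  # tip: drift -> 0
  expect_equal(kpp$a_fn(c(-5, 5)), c(1, 1))
  ac <- lineage_coeffs(wave_frame_model("allen_cahn", s = 0.5))
  x <- seq(-5, 5, 0.5)
  expect_equal(ac$drift_fn(x), 0.5 - 2 * exp(x) / (1 + exp(x)))
  pme <- lineage_coeffs(wave_frame_model("pme_logistic"))
  xi <- -1e-4
  expect_equal(pme$a_fn(xi), 1 - exp(xi / 2))
  expect_lt(pme$a_fn(xi), 1e-4)                          # vanishes at the front
  expect_equal(pme$drift_fn(xi), 1 - 2 * exp(xi / 2))    # -> -1
  expect_equal(pme$drift_fn(-1e-6), -1, tolerance = 1e-5)
})

test_that("zero-drift unit-diffusion lineages spread like Brownian motion", {
  set.seed(12)
  src <- stationary_source(phi_fn = 1, sigma2 = 2)  # a = 1, drift = 0
  cf <- lineage_coeffs(src)
  ens <- simulate_lineage(cf, x0 = 0, S = 1, dt = 1e-3, n_paths = 2000,
                          record_every = 0.5)
  v <- var(ens$paths[, ncol(ens$paths)])
  expect_equal(v, 2, tolerance = 0.15)  # Var = 2 a S
})

test_that("closed-form speed measures are normalised and correct", {
  ## porous-medium: integral of e^xi (1 - e^{xi/2}) over xi < 0 is 1/3
  q <- pracma::integral(function(z) exp(z) * (1 - exp(z / 2)), -60, 0)
  expect_equal(q, 1 / 3, tolerance = 1e-9)
  sdp <- stationary_density(wave_frame_model("pme_logistic"))
  dxg <- diff(sdp$x[1:2])
  expect_equal(sum(sdp$density) * dxg, 1, tolerance = 1e-4)
  expect_equal(approx(sdp$x, sdp$density, xout = -2)$y,
               3 * exp(-2) * (1 - exp(-1)), tolerance = 1e-4)
  ## Allen-Cahn with s = 1 is the standard logistic density (mean 0)
  sda <- stationary_density(wave_frame_model("allen_cahn", s = 1))
  dxg <- diff(sda$x[1:2])
  expect_equal(sum(sda$density) * dxg, 1, tolerance = 1e-6)
  expect_equal(sum(sda$x * sda$density) * dxg, 0, tolerance = 1e-6)
  expect_equal(sda$density[which.min(abs(sda$x))], dlogis(0), tolerance = 1e-3)
  ## Fisher-KPP: no stationary distribution
  expect_false(stationary_density(wave_frame_model("fisher_kpp"))$integrable)
})

test_that("numeric speed-measure route matches the closed form", {
  ac <- wave_frame_model("allen_cahn", s = 0.7)
  grid <- seq(-25, 25, length.out = 4001)
  num <- stationary_density(lineage_coeffs(ac), grid)
  expect_true(num$integrable)
  closed <- exp(0.7 * grid) / (1 + exp(grid))^2 / beta(0.7, 1.3)
  expect_lt(max(abs(num$density - closed)), 1e-3 * max(closed))
})

test_that("discretised lineage generator satisfies detailed balance", {
  ac <- lineage_coeffs(wave_frame_model("allen_cahn", s = 0.5))
  x <- seq(-8, 8, by = 0.01)
  a <- ac$a_fn(x); b <- ac$drift_fn(x)
  dxg <- 0.01
  ## nearest-neighbour chain: q(i -> i+1) = a/dx^2 + b/(2dx), etc.
  qup <- a / dxg^2 + b / (2 * dxg)
  qdn <- a / dxg^2 - b / (2 * dxg)
  m <- stationary_density(ac, x)$density
  n <- length(x)
  lhs <- m[-n] * qup[-n]
  rhs <- m[-1] * qdn[-1]
  expect_lt(max(abs(lhs - rhs) / pmax(lhs, rhs)), 1e-3)
})

test_that("empirical generator of simulated paths matches the coefficients", {
  set.seed(22)
  ac <- lineage_coeffs(wave_frame_model("allen_cahn", s = 0.5))
  x0 <- 0.3; s <- 0.05
  ens <- simulate_lineage(ac, x0 = x0, S = s, dt = 1e-3, n_paths = 40000,
                          record_every = s)
  f <- function(x) sin(x)
  incr <- f(ens$paths[, ncol(ens$paths)]) - f(x0)
  gen_emp <- mean(incr) / s
  gen_true <- ac$a_fn(x0) * (-sin(x0)) + ac$drift_fn(x0) * cos(x0)
  se <- sd(incr) / s / sqrt(40000)
  expect_lt(abs(gen_emp - gen_true), 3 * se + 0.05 * abs(gen_true))
})

test_that("reproductive value is constant in homogeneous models and tracks 1/lambda", {
  grid <- seq(0, 10, length.out = 501)
  hom <- stationary_source(phi_fn = 1, r_fn = 1, gamma_fn = 1, sigma2 = 2,
                           period = 10)
  ## two-patch lambda rescaling: r~ = lambda r, F~ = lambda F leaves the
  ## profile unchanged but reweights pi by 1/lambda
  lam <- function(x) ifelse(x < 5, 0.5, 1)
  resc <- stationary_source(phi_fn = 1, r_fn = lam, gamma_fn = 1, sigma2 = 2,
                            period = 10)
  rv_h <- reproductive_value(hom, grid)
  rv_r <- reproductive_value(resc, grid)
  expect_lt(diff(range(rv_h$value)), 1e-9)
  ratio <- rv_r$value / rv_h$value
  inner1 <- grid > 0.5 & grid < 4.5; inner2 <- grid > 5.5 & grid < 9.5
  expect_equal(mean(ratio[inner1]) / mean(ratio[inner2]),
               (1 / 0.5) / (1 / 1), tolerance = 1e-6)
})

test_that("lambda-rescaled dynamics are distinguishable from lineage occupation", {
  set.seed(32)
  grid <- seq(0, 10, length.out = 501)
  lam <- function(x) ifelse(x < 5, 0.5, 1)
  hom <- stationary_source(phi_fn = 1, sigma2 = 2, period = 10)
  resc <- stationary_source(phi_fn = 1, r_fn = lam, sigma2 = 2, period = 10)
  occ <- function(src) {
    cf <- lineage_coeffs(src)
    ens <- simulate_lineage(cf, x0 = 2, S = 150, dt = 5e-3, n_paths = 25,
                            record_every = 0.5)
    as.vector(ens$paths[, ens$s > 30])
  }
  s1 <- occ(hom); s2 <- occ(resc)
  ## same stationary profile (phi = 1 for both) but different occupation law:
  ## lineages linger where lambda is small
  expect_lt(ks.test(s1, s2)$p.value, 0.001)
  expect_gt(mean(s2 < 5), mean(s1 < 5))
})
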