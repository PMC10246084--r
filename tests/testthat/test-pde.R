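test_that("pure diffusion reproduces the heat kernel and conserves mass", {
  dx <- 0.05
  xg <- periodic_grid(800, dx)  # length 40
  phi0 <- density_field(xg, exp(-(xg - 20)^2 / 2), boundary = "periodic")
  tr <- solve_local_rd(phi0, rate_fn("constant", c = 0), sigma2 = 2,
                       T = 1, dt = 4e-4, record_every = 1)
  exact <- sqrt(2 * pi) * dnorm(xg - 20, sd = sqrt(3))  # variance 1 + 2t
  expect_lt(max(abs(tr$values[[length(tr$values)]] - exact)), 1e-4)
  expect_lt(abs(field_mass(snapshot_field(tr)) / field_mass(phi0) - 1), 1e-6)
})

test_that("equilibria are stationary for the local and nonlocal solvers", {
  dx <- 0.1
  xg <- periodic_grid(200, dx)
  ones <- density_field(xg, rep(1, 200), boundary = "periodic")
  tr <- solve_local_rd(ones, rate_fn("logistic_F"), sigma2 = 2, T = 0.1,
                       dt = 1e-3, record_every = 0.1)
  expect_lt(max(abs(tr$values[[length(tr$values)]] - 1)), 1e-12)
  dem <- logistic_dem(5, 10)
  disp <- dispersal_spec(theta = 5, sigma2 = 2)
  trn <- solve_nonlocal(ones, dem, disp, T = 0.1, dt = 1e-3,
                        record_every = 0.1)
  expect_lt(max(abs(trn$values[[length(trn$values)]] - 1)), 1e-12)
  trp <- solve_pme_logistic(ones, T = 0.1, record_every = 0.1)
  expect_lt(max(abs(trp$values[[length(trp$values)]] - 1)), 1e-12)
})

test_that("CFL violations error with a suggested step", {
  xg <- periodic_grid(100, 0.1)
  f <- density_field(xg, rep(1, 100), boundary = "periodic")
  expect_error(solve_local_rd(f, rate_fn("logistic_F"), sigma2 = 2,
                              T = 1, dt = 0.01),
               "CFL")
})

test_that("wave profiles match their closed forms", {
  ac <- wave_frame_model("allen_cahn", s = 0.5)
  expect_equal(wave_profile(ac, 0), 0.5)
  pme <- wave_frame_model("pme_logistic")
  expect_equal(wave_profile(pme, 0), 0)
  expect_equal(wave_profile(pme, 1.7), 0)          # zero beyond the front
  expect_equal(wave_profile(pme, -2 * log(2)), 0.5)
  expect_true(all(diff(wave_profile(ac, seq(-10, 10, 0.1))) < 0))
  kpp <- wave_frame_model("fisher_kpp")
  w <- wave_profile(kpp, seq(-20, 20, 0.1))
  expect_true(all(diff(w) <= 1e-12))
  expect_equal(wave_profile(kpp, 0), 0.5, tolerance = 1e-6)
})

test_that("travelling-wave residuals vanish at the true speed only", {
  pme <- wave_frame_model("pme_logistic")
  expect_lt(travelling_wave_residual(pme, derivatives = "analytic"), 1e-8)
  expect_gt(travelling_wave_residual(pme, c = 2, derivatives = "analytic"), 0.1)
  ac <- wave_frame_model("allen_cahn", s = 0.5)
  expect_lt(travelling_wave_residual(ac, derivatives = "analytic"), 1e-12)
  expect_lt(travelling_wave_residual(ac, derivatives = "fd", dx = 1e-3), 1e-6)
  ## the relaxed Fisher-KPP table solves its co-moving ODE approximately
  kpp <- wave_frame_model("fisher_kpp")
  expect_lt(travelling_wave_residual(kpp, x = seq(-10, 5, 0.01), dx = 0.05),
            0.01)
})

test_that("front position and speed estimation are exact on synthetic fronts", {
  xg <- seq(0, 20, by = 0.01)
  ac <- wave_frame_model("allen_cahn", s = 0.5)
  f <- density_field(xg, wave_profile(ac, xg - 7), boundary = "neumann")
  expect_equal(front_position(f, 0.5), 7, tolerance = 1e-10)
  pme <- wave_frame_model("pme_logistic")
  fp <- density_field(xg, wave_profile(pme, xg - 5), boundary = "neumann")
  expect_equal(front_position(fp, 0.5), 5 - 2 * log(2), tolerance = 1e-4)
  ramp <- density_field(xg, pmax(1 - xg / 10, 0), boundary = "neumann")
  expect_equal(front_position(ramp, 0.3), 7, tolerance = 1e-10)
  expect_error(front_position(density_field(xg, rep(0.1, length(xg)),
                                            boundary = "neumann")),
               "front not found")
  ## exact translating fronts: x(t) = 3 + 2t
  tt <- seq(0, 5, by = 0.5)
  traj <- structure(list(
    times = tt,
    values = lapply(tt, function(t) wave_profile(ac, xg - 3 - 2 * t)),
    x = xg, dx = 0.01, boundary = "neumann", clipped_mass = 0),
    class = "field_trajectory")
  est <- estimate_speed(traj, 0.5, c(0, 5))
  expect_equal(est$speed, 2, tolerance = 1e-9)
})

test_that("porous-medium fronts have compact support, unlike Fisher-KPP", {
  dx <- 0.05
  xg <- periodic_grid(400, dx)  # length 20
  bump <- ifelse(abs(xg - 5) < 2, 0.8, 0)
  trp <- solve_pme_logistic(density_field(xg, bump, boundary = "neumann"),
                            T = 0.5, record_every = 0.5)
  edge <- max(xg[trp$values[[length(trp$values)]] > 1e-8])
  expect_lt(edge, 5 + 2 + 1.5)  # support grew by a bounded amount
  trf <- solve_local_rd(density_field(xg, bump, boundary = "neumann"),
                        rate_fn("logistic_F"), sigma2 = 2, T = 0.5,
                        dt = 4e-4, record_every = 0.5)
  expect_true(all(trf$values[[length(trf$values)]] > 0))  # instant support
})

test_that("ordered Fisher-KPP initial conditions stay ordered", {
  set.seed(91)
  dx <- 0.1
  xg <- periodic_grid(200, dx)
  base <- 0.5 + 0.3 * sin(2 * pi * xg / 20) * runif(1)
  lower <- density_field(xg, base, boundary = "periodic")
  upper <- density_field(xg, base + 0.2 * runif(200), boundary = "periodic")
  trl <- solve_local_rd(lower, rate_fn("logistic_F"), 2, T = 0.5, dt = 1e-3,
                        record_every = 0.5)
  tru <- solve_local_rd(upper, rate_fn("logistic_F"), 2, T = 0.5, dt = 1e-3,
                        record_every = 0.5)
  expect_true(all(tru$values[[length(tru$values)]] >=
                    trl$values[[length(trl$values)]] - 1e-12))
})

test_that("estimated Fisher-KPP speed converges under grid refinement", {
  ## over a finite window the minimal-speed front still carries its slowly
  ## decaying (logarithmic-in-time) speed deficit, so the continuum value on
  ## [20, 50] sits a couple of percent below 2; refinement must converge to
  ## it monotonically, with differences shrinking roughly like O(dx)
  speeds <- vapply(c(0.4, 0.2, 0.1), function(dx) {
    xg <- seq(0, 150 - dx, by = dx) + dx / 2
    phi0 <- density_field(xg, as.numeric(xg < 10), boundary = "neumann")
    tr <- solve_local_rd(phi0, rate_fn("logistic_F"), sigma2 = 2,
                         T = 50, dt = 0.19 * dx^2, record_every = 1)
    estimate_speed(tr, 0.5, c(20, 50))$speed
  }, 0)
  steps <- abs(diff(speeds))
  expect_lt(steps[2], steps[1])             # successive refinements converge
  expect_equal(speeds[3], 2, tolerance = 0.04)
  expect_true(all(abs(speeds - 2) < 0.05))
})

test_that("nonlocal solutions approach local ones as the kernel shrinks (single width)", {
  dx <- 0.05
  xg <- periodic_grid(400, dx)  # length 20
  bump <- 0.8 * exp(-(xg - 10)^2 / 2)
  loc <- solve_local_rd(density_field(xg, bump, boundary = "periodic"),
                        rate_fn("logistic_F"), sigma2 = 2, T = 0.5, dt = 4e-4,
                        record_every = 0.5)
  kF <- kernel_spec("gaussian", 0.2)
  dem <- demography("constant", "constant", "logistic_F", theta = 10, N = 100,
                    kernels = list(gamma = gauss1(), r = gauss1(), F = kF))
  disp <- dispersal_spec(theta = 10, sigma2 = 2)
  nl <- solve_nonlocal(density_field(xg, bump, boundary = "periodic"),
                       dem, disp, T = 0.5, dt = 4e-4, record_every = 0.5)
  l1 <- sum(abs(nl$values[[length(nl$values)]] -
                  loc$values[[length(loc$values)]])) * dx
  expect_lt(l1, 0.05)
})
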