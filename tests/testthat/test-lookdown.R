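test_that("closed-form level evolution matches its special cases", {
  expect_equal(evolve_level(2, 1, 0, log(2))$u, 1)       # pure decay
  expect_equal(evolve_level(2, 2, 1, 7.3)$u, 2)          # fixed point u = b/c
  expect_equal(evolve_level(2, 1, 1, log(4 / 3))$u, 3)
  e <- evolve_level(2, 1, 1, 1)
  expect_identical(e$u, Inf)
  expect_equal(e$escape_time, log(2))
})

test_that("closed-form level evolution agrees with an adaptive ODE solver", {
  skip_if_not_installed("deSolve")
  set.seed(15)
  n <- 200
  u0 <- runif(n, 0.05, 20)
  b <- runif(n, -3, 3); b[sample(n, 10)] <- 0
  cc <- runif(n, 0, 2); cc[sample(n, 10)] <- 0
  dt <- runif(n, 0.01, 3)
  for (i in seq_len(n)) {
    ## independent route: integrate v' = b v - c (v = 1/u) with lsoda and
    ## detect escape by a root at v = 0
    sol <- deSolve::lsoda(
      y = c(v = 1 / u0[i]), times = c(0, dt[i]),
      func = function(t, y, p) list(b[i] * y[1] - cc[i]),
      rtol = 1e-13, atol = 1e-16,
      events = list(func = function(t, y, p) y, root = TRUE,
                    terminalroot = 1),
      rootfunc = function(t, y, p) y[1])
    got <- evolve_level(u0[i], b[i], cc[i], dt[i])
    t_root <- attr(sol, "troot")
    if (!is.null(t_root) && length(t_root) > 0 && t_root[1] < dt[i] - 1e-12) {
      expect_identical(got$u, Inf)
      expect_equal(got$escape_time, t_root[1], tolerance = 1e-8)
    } else {
      vend <- unname(sol[nrow(sol), "v"])
      expect_false(is.infinite(got$u) && vend > 1e-8)
      expect_equal(got$u, 1 / vend, tolerance = 1e-8)
    }
  }
})

test_that("level-ODE coefficients: constant r collapses the dispersal integral", {
  set.seed(25)
  dom <- domain_spec(1, 10, "periodic")
  dem <- logistic_dem(5, 20)
  disp <- dispersal_spec(theta = 5, sigma2 = 1)
  pop <- point_population(runif(200, 0, 10), 20, dom)
  x <- c(1, 5, 8.5)
  cf <- level_coeffs(x, pop, dem, disp)
  mF <- local_density(pop, dem$kernels$F, x)
  expect_equal(cf$b_level, 1 - mF)                  # b = F exactly
  mg <- local_density(pop, dem$kernels$gamma, x)
  expect_equal(cf$c_level, (5 / 20) * dem$gamma_fn(x, mg))
})

test_that("spatially varying r: quadrature matches a Monte-Carlo oracle", {
  set.seed(35)
  dom <- domain_spec(1, 40, "periodic")
  r_sp <- rate_fn("spatial", fn = function(x, m) 1 / (1 + (x - 20)^2))
  dem <- demography("constant", r_sp, rate_fn("constant", c = 0),
                    theta = 100, N = 50, kernels = gauss1())
  disp <- dispersal_spec(theta = 100, sigma2 = 1)
  pop <- point_population(runif(100, 0, 40), 50, dom)
  x <- 21.3
  cf <- level_coeffs(x, pop, dem, disp, M = 40)
  ## oracle: theta * E[r(y) - r(x)] with y ~ N(x, 1/theta), 1e6 draws
  nmc <- 1e6
  y <- x + rnorm(nmc) / 10
  rfun <- function(z) 1 / (1 + (z - 20)^2)
  smp <- 100 * (rfun(y) - rfun(x))
  se <- sd(smp) / sqrt(nmc)
  expect_lt(abs(cf$b_level - mean(smp)), 3 * se)
})

test_that("without births a single level evolves deterministically", {
  set.seed(45)
  dom <- domain_spec(1, 5, "periodic")
  ## gamma = 0: no births; F = -1 gives b = -1, c = 0, so u(t) = u0 e^{t}
  dem <- demography(rate_fn("constant", c = 0), "constant",
                    rate_fn("constant", c = -1),
                    theta = 5, N = 10, kernels = gauss1())
  disp <- dispersal_spec(theta = 5, sigma2 = 1)
  st0 <- lookdown_state(2.5, "finite_N", N = 10, levels = 1, domain = dom)
  run <- lookdown_run(st0, dem, disp, T = 1, record_every = 1)
  expect_equal(sum(run$events$type == "birth"), 0)
  expect_equal(run$state$levels, exp(1), tolerance = 1e-9)
  ## run long enough and the level crosses N: the individual dies
  run2 <- lookdown_run(st0, dem, disp, T = 3, record_every = 3)
  expect_equal(length(run2$state$positions), 0)
  expect_equal(sum(run2$events$type == "death"), 1)
  expect_equal(run2$events$time[run2$events$type == "death"], log(10),
               tolerance = 1e-9)
})

test_that("projection recovers the alive-position multiset implied by the event log", {
  set.seed(55)
  dom <- domain_spec(1, 3, "periodic")
  dem <- logistic_dem(3, 12)
  disp <- dispersal_spec(theta = 3, sigma2 = 1)
  st0 <- lookdown_state(runif(36, 0, 3), "finite_N", N = 12, domain = dom)
  run <- lookdown_run(st0, dem, disp, T = 1.5, record_every = 1.5)
  pop <- project(run$state)
  expect_s3_class(pop, "point_population")
  expect_equal(total_mass(pop), length(run$state$positions) / 12)
  ## individuals never move: founders + birth locations = alive + deaths
  ev <- run$events
  appeared <- c(run$founders$x0, ev$x_child[ev$type == "birth"])
  gone <- ev$x_parent[ev$type == "death"]
  expect_equal(sort(c(pop$positions, gone)), sort(appeared), tolerance = 1e-12)
  ## empty state projects to the empty population
  st_empty <- lookdown_state(numeric(0), "finite_N", N = 12, domain = dom)
  expect_equal(pop_size(project(st_empty)), 0)
})

test_that("sampling the k lowest levels is a uniform spatial sample", {
  set.seed(65)
  dom <- domain_spec(1, 10, "periodic")
  st <- lookdown_state(runif(50, 0, 10), "finite_N", N = 20, domain = dom)
  all50 <- sample_k_lowest(st, c(0, 10), 50)
  expect_equal(nrow(all50), 50)
  expect_true(all(diff(all50$level) >= 0))
  expect_error(sample_k_lowest(st, c(0, 1), 40), "fewer than k")
  one <- sample_k_lowest(st, c(0, 10), 1)
  expect_equal(one$level, min(st$levels))
  ## over replicate level assignments, the lowest-level individual in a fixed
  ## region is uniform among the individuals there (chi-square over atoms)
  xs <- runif(40, 0, 10)
  counts <- integer(40)
  for (r in 1:2000) {
    st <- lookdown_state(xs, "finite_N", N = 20,
                         levels = runif(40, 0, 20), domain = dom)
    w <- sample_k_lowest(st, c(0, 10), 1)
    counts[which.min(abs(xs - w$position))] <- counts[
      which.min(abs(xs - w$position))] + 1L
  }
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("lineage tracing is constant without births and jumps per the labeling rule", {
  set.seed(75)
  dom <- domain_spec(1, 5, "periodic")
  dem0 <- demography(rate_fn("constant", c = 0), "constant",
                     rate_fn("constant", c = 0),
                     theta = 5, N = 10, kernels = gauss1())
  disp <- dispersal_spec(theta = 5, sigma2 = 1)
  st0 <- lookdown_state(c(1, 2.5), "finite_N", N = 10,
                        levels = c(1, 2), domain = dom)
  run <- lookdown_run(st0, dem0, disp, T = 1, record_every = 1)
  tl <- trace_lineage(run, "1", s = 1)
  expect_true(all(tl$position == 1))
  ## with dynamics: every traced path starts at the sampled position and ends
  ## at its founder's initial position
  dem <- logistic_dem(3, 12)
  st1 <- lookdown_state(runif(36, 0, 3), "finite_N", N = 12,
                        domain = domain_spec(1, 3, "periodic"))
  run1 <- lookdown_run(st1, dem, disp, T = 1.5, record_every = 1.5)
  for (lab in run1$state$labels[1:5]) {
    tl <- trace_lineage(run1, lab, s = 1.5)
    i <- match(lab, run1$state$labels)
    expect_equal(tl$position[1], run1$state$positions[i])
    root <- strsplit(lab, ".", fixed = TRUE)[[1]][1]
    expect_equal(tl$position[nrow(tl)],
                 run1$founders$x0[match(root, run1$founders$label)])
    ## every recorded change point after the sampling time is a birth event
    ## on the ancestry (jumps only happen at birth events)
    expect_true(all(tl$time[-1] %in% c(run1$events$time, 0)))
  }
})

test_that("genealogy export produces the forced topologies and valid ultrametric trees", {
  skip_if_not_installed("ape")
  ## hand-built history: founder 1; offspring 1.1 at t = 0.4 (kappa = 0)
  fake <- structure(list(
    state = list(labels = c("1", "1.1")),
    events = data.frame(time = 0.4, type = "birth", parent_label = "1",
                        child_label = "1.1", x_parent = 2, x_child = 2.3,
                        u_new = 5, kappa = 0L, stringsAsFactors = FALSE),
    founders = data.frame(label = "1", x0 = 2, stringsAsFactors = FALSE),
    T = 1), class = "lookdown_run")
  expect_equal(export_genealogy(fake, c("1")), "(1:1);")
  cherry <- export_genealogy(fake, c("1", "1.1"))
  tr <- ape::read.tree(text = cherry)
  expect_equal(sort(tr$tip.label), c("1", "1_1"))
  d <- ape::node.depth.edgelength(tr)
  expect_equal(max(d), 1, tolerance = 1e-9)
  expect_lt(diff(range(d[1:2])), 1e-9)  # cherry leaves at equal depth T
  ## simulated history: all trees parse, are ultrametric at depth T
  set.seed(85)
  dom <- domain_spec(1, 3, "periodic")
  dem <- logistic_dem(3, 12)
  disp <- dispersal_spec(theta = 3, sigma2 = 1)
  st0 <- lookdown_state(runif(36, 0, 3), "finite_N", N = 12, domain = dom)
  run <- lookdown_run(st0, dem, disp, T = 2, record_every = 2)
  smp <- sample_k_lowest(run$state, c(0, 3), 8)
  nwk <- export_genealogy(run, smp$label)
  for (s in nwk) {
    tr <- ape::read.tree(text = s)
    expect_false(is.null(tr))
    dep <- ape::node.depth.edgelength(tr)
    tipd <- dep[seq_len(length(tr$tip.label))]
    expect_lt(diff(range(c(tipd, 2))), 1e-9)
  }
})

test_that("limit mode: no new lines at alpha = 0; exponential level gaps at alpha > 0", {
  set.seed(95)
  dom <- domain_spec(1, 10, "periodic")
  dem <- logistic_dem(5, 10)
  disp <- dispersal_spec(theta = 5, sigma2 = 1)
  st0 <- lookdown_state(runif(80, 0, 10), "limit", alpha = 0, u_max = 8,
                        domain = dom)
  run0 <- lookdown_run(st0, dem, disp, T = 0.5, record_every = 0.5,
                       dt_max = 0.01)
  expect_equal(sum(run0$events$type == "birth"), 0)
  ## single parent, alpha > 0: new-line levels form a Poisson process above
  ## the parent's level with intensity 2*alpha*gamma*r per unit level and
  ## time, so sorted-level spacings over a window T are Exp(2*alpha*T)
  alpha <- 2; Tw <- 0.1; u_max <- 400
  gaps <- c()
  for (rep in 1:3) {
    st1 <- lookdown_state(5, "limit", alpha = alpha, u_max = u_max,
                          levels = 0.5, domain = dom)
    run1 <- lookdown_run(st1, dem, disp, T = Tw, record_every = Tw,
                         dt_max = 0.002)
    kids <- run1$events[run1$events$type == "birth" &
                          run1$events$parent_label == "1", ]
    ## stay above the parent's (slightly drifting) level
    lv <- sort(kids$u_new[kids$u_new > 1])
    gaps <- c(gaps, diff(lv))
  }
  expect_gt(length(gaps), 60)
  expect_gt(ks.test(gaps, "pexp", 2 * alpha * Tw)$p.value, 0.01)
})

test_that("raising F pointwise pushes levels down (stochastic monotonicity)", {
  dom <- domain_spec(1, 4, "periodic")
  disp <- dispersal_spec(theta = 4, sigma2 = 1)
  dem_lo <- logistic_dem(4, 12)
  dem_hi <- demography("constant", "constant",
                       rate_fn("tabulated", m = c(0, 20),
                               values = c(1.4, -18.6)),  # F = 1.4 - m
                       theta = 4, N = 12, kernels = gauss1())
  mean_lev <- function(dem, seed) {
    set.seed(seed)
    out <- c()
    for (i in 1:40) {
      st0 <- lookdown_state(runif(48, 0, 4), "finite_N", N = 12, domain = dom)
      run <- lookdown_run(st0, dem, disp, T = 1, record_every = 1)
      out <- c(out, run$state$levels)
    }
    mean(out)
  }
  expect_lt(mean_lev(dem_hi, 105), mean_lev(dem_lo, 105))
})
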