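## Kernel-smoothed densities at the atoms of a 1-d population, by direct
## summation over all pairs through the minimal image.  Returns a list with
## one density vector per (distinct) kernel.
atom_densities_direct <- function(pop, kernels) {
  n <- pop_size(pop)
  if (n == 0L) return(lapply(kernels, function(k) numeric(0)))
  if (pop$domain$dim == 1L) {
    d <- outer(pop$positions, pop$positions, "-")
    if (pop$domain$boundary == "periodic")
      d <- min_image(d, pop$domain$lengths[1])
    ## evaluate each distinct kernel once
    keys <- vapply(kernels, function(k) paste(k$family, k$scale), "")
    dens_by_key <- lapply(unique(keys), function(key) {
      k <- kernels[[match(key, keys)]]
      rowSums(matrix(kernel_value(k, d), nrow = n)) / pop$N
    })
    names(dens_by_key) <- unique(keys)
    stats::setNames(lapply(keys, function(key) dens_by_key[[key]]),
                    names(kernels))
  } else {
    lapply(kernels, function(k) local_density(pop, k, pop$positions))
  }
}

## FFT route (1-d periodic): bin atoms with cloud-in-cell weights, convolve
## with each kernel on the grid, and return linear interpolators.
density_field_fft <- function(pop, k, dx) {
  L <- pop$domain$lengths[1]
  n_cells <- max(8L, round(L / dx))
  dx <- L / n_cells
  xg <- (seq_len(n_cells) - 1) * dx
  dep <- numeric(n_cells)
  if (pop_size(pop) > 0L) {
    u <- pop$positions / dx
    i0 <- floor(u)
    f <- u - i0
    i0 <- (as.integer(i0) %% n_cells) + 1L
    i1 <- (i0 %% n_cells) + 1L
    add <- function(idx, w) {
      tab <- tapply(w, idx, sum)
      dep[as.integer(names(tab))] <<- dep[as.integer(names(tab))] + as.numeric(tab)
    }
    add(i0, (1 - f) / (pop$N * dx))
    add(i1, f / (pop$N * dx))
  }
  kd <- kernel_grid(k, xg, L)
  vals <- fft_convolve(dep, stats::fft(kd), dx)
  density_field(xg, pmax(vals, 0), boundary = "periodic", time = pop$time)
}

## periodic linear interpolation of a density_field at query points
interp_periodic <- function(field, xq) {
  L <- length(field$x) * field$dx
  u <- (xq %% L) / field$dx
  i0 <- floor(u)
  f <- u - i0
  n <- length(field$x)
  i0 <- (as.integer(i0) %% n) + 1L
  i1 <- (i0 %% n) + 1L
  field$values[i0] * (1 - f) + field$values[i1] * f
}

#' Grid-binned kernel-smoothed density of a point population
#'
#' Deposits mass \code{1/N} per atom onto a regular grid (cloud-in-cell
#' weights, exactly mass-conserving) and convolves with the kernel by FFT.
#' 1-d periodic domains only.
#'
#' @param pop a \code{\link{point_population}}.
#' @param dx grid spacing (must not exceed the kernel scale).
#' @param k a \code{\link{kernel_spec}}.
#' @return a \code{\link{density_field}} whose integral equals the total
#'   population mass.
#' @export
binned_density <- function(pop, dx, k) {
  stopifnot(inherits(pop, "point_population"), pop$domain$dim == 1L)
  if (dx > k$scale + 1e-12)
    stop("grid spacing dx must not exceed the kernel scale")
  density_field_fft(pop, k, dx)
}

ibm_trajectory <- function(times, n, mass, mean_density, snapshots, meta) {
  structure(list(times = times, n = n, mass = mass,
                 mean_density = mean_density, snapshots = snapshots,
                 meta = meta),
            class = "ibm_trajectory")
}

#' @export
print.ibm_trajectory <- function(x, ...) {
  cat(sprintf(
    "<ibm_trajectory: %s, %d records, t in [%g, %g], final n = %d>\n",
    x$meta$method, length(x$times), min(x$times), max(x$times),
    utils::tail(x$n, 1)))
  invisible(x)
}

#' Exact event-driven simulation of the individual-based model
#'
#' Simulates the scaled spatial birth-death process: each individual at
#' \eqn{x_i} gives birth at rate \eqn{\theta\gamma(x_i, m_\gamma)} and dies at
#' rate \eqn{\theta\mu_\theta(x_i,\cdot)}, with all local densities
#' recomputed exactly at every event.  A newborn dispersing to \eqn{y} is
#' retained with probability \eqn{r(y, m_r(y))}, the density being evaluated
#' on the pre-birth population (the parent counts, the juvenile does not).
#' Time is scaled time.
#'
#' @param pop0 initial \code{\link{point_population}}.
#' @param dem a \code{\link{demography}}.
#' @param disp a \code{\link{dispersal_spec}}.
#' @param T scaled-time horizon.
#' @param record_every interval between recorded summaries.
#' @param n_max explosion guard (default \code{100 * N * volume}).
#' @param store_snapshots if TRUE, store atom positions at record times.
#' @return an \code{ibm_trajectory} with per-record time, count, total mass,
#'   and mean smoothed density at atoms.
#' @export
gillespie_run <- function(pop0, dem, disp, T, record_every = T / 20,
                          n_max = NULL, store_snapshots = FALSE) {
  stopifnot(inherits(pop0, "point_population"))
  if (is.null(n_max))
    n_max <- ceiling(100 * pop0$N * prod(pop0$domain$lengths))
  domain <- pop0$domain
  pos <- pop0$positions
  theta <- dem$theta
  rec_t <- numeric(0); rec_n <- integer(0); rec_m <- numeric(0)
  rec_md <- numeric(0); snaps <- if (store_snapshots) list() else NULL
  t <- pop0$time
  t_end <- pop0$time + T
  next_rec <- t
  record <- function(t, pos, md) {
    rec_t <<- c(rec_t, t); rec_n <<- c(rec_n, length(pos))
    rec_m <<- c(rec_m, length(pos) / pop0$N)
    rec_md <<- c(rec_md, md)
    if (store_snapshots) snaps[[length(snaps) + 1L]] <<- pos
  }
  repeat {
    n <- length(pos)
    if (n == 0L) {
      while (next_rec <= t_end + 1e-12) {
        record(next_rec, pos, NA_real_); next_rec <- next_rec + record_every
      }
      break
    }
    if (n > n_max)
      stop(sprintf(
        "population exploded past n_max = %d at t = %g (check that mu_theta >= 0 and gamma is capped)",
        n_max, t))
    pop <- point_population(pos, pop0$N, domain, time = t)
    dens <- atom_densities_direct(pop, dem$kernels)
    birth <- theta * dem$gamma_fn(pos, dens$gamma)
    death <- theta * death_rate(dem, pos, dens$r, dens$gamma, dens$F)
    R <- sum(birth) + sum(death)
    dt_ev <- stats::rexp(1, R)
    while (next_rec <= min(t + dt_ev, t_end) + 1e-12) {
      record(next_rec, pos, mean(dens$gamma))
      next_rec <- next_rec + record_every
    }
    t <- t + dt_ev
    if (t > t_end) break
    i <- sample.int(n, 1L, prob = birth + death)
    if (stats::runif(1) < birth[i] / (birth[i] + death[i])) {
      y <- sample_dispersal(disp, if (domain$dim == 1L) pos[i] else pos[i, ],
                            domain)
      m_r_y <- local_density(pop, dem$kernels$r, y)
      if (stats::runif(1) < dem$r_fn(y, m_r_y)) {
        pos <- if (domain$dim == 1L) c(pos, y) else rbind(pos, y)
      }
    } else {
      pos <- if (domain$dim == 1L) pos[-i] else pos[-i, , drop = FALSE]
    }
  }
  ibm_trajectory(rec_t, rec_n, rec_m, rec_md, snaps,
                 meta = list(method = "gillespie", density_mode = "per_event",
                             theta = theta, N = pop0$N))
}

#' One synchronous time step of the discrete-time individual-based model
#'
#' Every individual independently reproduces with probability
#' \eqn{1 - e^{-\gamma(x,m)\,\theta\,dt}} and dies with probability
#' \eqn{1 - e^{-\mu_\theta(x,m)\,\theta\,dt}}, all densities evaluated once
#' on the start-of-step population; offspring disperse and establish exactly
#' as in \code{\link{gillespie_run}} and are appended after all decisions.
#' \code{dt} is in scaled time, so for the porous-medium parameterisation
#' (\eqn{r\equiv 1}, \eqn{\gamma = m}, \eqn{F = 1-m}) the probabilities
#' reduce to \eqn{p_b(m) = 1 - e^{-m\,d\tau}} and \eqn{p_d(m) = 1 -
#' e^{-(m(1+1/\theta)-1/\theta)\,d\tau}} with \eqn{d\tau = \theta\,dt} the
#' step in unscaled time units.
#'
#' @param pop a \code{\link{point_population}}.
#' @param dem a \code{\link{demography}}.
#' @param disp a \code{\link{dispersal_spec}}.
#' @param dt step length in scaled time.
#' @param density_mode \code{"direct"} (exact pairwise sums) or \code{"fft"}
#'   (grid-binned convolution, 1-d periodic only).
#' @param fft_dx grid spacing for the fft mode.
#' @return the population after one step.
#' @export
discrete_step <- function(pop, dem, disp, dt,
                          density_mode = c("direct", "fft"), fft_dx = 0.05) {
  density_mode <- match.arg(density_mode)
  n <- pop_size(pop)
  if (n == 0L) {
    pop$time <- pop$time + dt
    return(pop)
  }
  theta <- dem$theta
  pos <- pop$positions
  if (density_mode == "direct") {
    dens <- atom_densities_direct(pop, dem$kernels)
    r_at <- function(y) dem$r_fn(y, local_density(pop, dem$kernels$r, y))
  } else {
    stopifnot(pop$domain$dim == 1L, pop$domain$boundary == "periodic")
    flds <- list()
    key_of <- function(k) paste(k$family, k$scale)
    for (nm in c("gamma", "r", "F")) {
      key <- key_of(dem$kernels[[nm]])
      if (is.null(flds[[key]]))
        flds[[key]] <- density_field_fft(pop, dem$kernels[[nm]], fft_dx)
    }
    dens <- list(
      gamma = interp_periodic(flds[[key_of(dem$kernels$gamma)]], pos),
      r = interp_periodic(flds[[key_of(dem$kernels$r)]], pos),
      F = interp_periodic(flds[[key_of(dem$kernels$F)]], pos))
    r_field <- flds[[key_of(dem$kernels$r)]]
    r_at <- function(y) dem$r_fn(y, interp_periodic(r_field, y))
  }
  mu <- death_rate(dem, pos, dens$r, dens$gamma, dens$F)
  if (theta * dt * max(dem$gamma_fn(pos, dens$gamma), mu) > 0.5)
    warning("theta*dt times the realized rates is not small; ",
            "discrete-time probabilities are a coarse approximation",
            call. = FALSE)
  p_birth <- 1 - exp(-dem$gamma_fn(pos, dens$gamma) * theta * dt)
  p_death <- 1 - exp(-mu * theta * dt)
  u <- stats::runif(n)
  parents <- which(u < p_birth)
  survive <- stats::runif(n) >= p_death
  newpos <- if (pop$domain$dim == 1L) numeric(0) else NULL
  if (length(parents) > 0L) {
    py <- if (pop$domain$dim == 1L) pos[parents] else pos[parents, , drop = FALSE]
    if (pop$domain$dim == 1L) {
      y <- sample_dispersal(disp, py, pop$domain)
      keep <- stats::runif(length(y)) < r_at(y)
      newpos <- y[keep]
    } else {
      newpos <- NULL
      for (j in seq_len(nrow(py))) {
        y <- sample_dispersal(disp, py[j, ], pop$domain)
        if (stats::runif(1) < dem$r_fn(y, local_density(pop, dem$kernels$r,
                                                        matrix(y, ncol = 2))))
          newpos <- rbind(newpos, y)
      }
    }
  }
  pos2 <- if (pop$domain$dim == 1L) c(pos[survive], newpos) else
    rbind(pos[survive, , drop = FALSE], newpos)
  out <- point_population(pos2, pop$N, pop$domain, time = pop$time + dt)
  attr(out, "mean_density") <- mean(dens$gamma)
  out
}

#' Run the discrete-time individual-based model
#'
#' Repeatedly applies \code{\link{discrete_step}} and records per-step
#' summaries.
#'
#' @inheritParams discrete_step
#' @param pop0 initial population.
#' @param T scaled-time horizon.
#' @param record_every recording interval (scaled time; a multiple of
#'   \code{dt}).
#' @param n_max explosion guard.
#' @param store_snapshots keep atom positions at record times.
#' @return an \code{ibm_trajectory}.
#' @export
discrete_run <- function(pop0, dem, disp, T, dt, record_every = dt,
                         density_mode = c("direct", "fft"), fft_dx = 0.05,
                         n_max = NULL, store_snapshots = FALSE) {
  density_mode <- match.arg(density_mode)
  if (is.null(n_max))
    n_max <- ceiling(100 * pop0$N * prod(pop0$domain$lengths))
  nstep <- round(T / dt)
  stride <- max(1L, round(record_every / dt))
  pop <- pop0
  rec_t <- pop0$time; rec_n <- pop_size(pop0); rec_m <- total_mass(pop0)
  rec_md <- NA_real_
  snaps <- if (store_snapshots) list(pop0$positions) else NULL
  for (s in seq_len(nstep)) {
    pop <- discrete_step(pop, dem, disp, dt, density_mode, fft_dx)
    if (pop_size(pop) > n_max)
      stop(sprintf("population exploded past n_max = %d at t = %g",
                   n_max, pop$time))
    if (s %% stride == 0L || s == nstep) {
      rec_t <- c(rec_t, pop$time)
      rec_n <- c(rec_n, pop_size(pop))
      rec_m <- c(rec_m, total_mass(pop))
      rec_md <- c(rec_md, attr(pop, "mean_density"))
      if (store_snapshots) snaps[[length(snaps) + 1L]] <- pop$positions
    }
  }
  out <- ibm_trajectory(rec_t, rec_n, rec_m, rec_md, snaps,
                        meta = list(method = "discrete",
                                    density_mode = density_mode,
                                    dt = dt, theta = dem$theta, N = pop0$N))
  out$final <- pop
  out
}
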