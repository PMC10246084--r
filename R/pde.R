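#' Gridded density field
#'
#' A 1-d regular-lattice density used by the PDE solvers.
#'
#' @param x cell-centre coordinates (regular spacing).
#' @param values nonnegative densities, same length as \code{x}.
#' @param boundary \code{"periodic"} or \code{"neumann"}.
#' @param time current time.
#' @return an object of class \code{density_field}.
#' @export
density_field <- function(x, values, boundary = c("periodic", "neumann"),
                          time = 0) {
  boundary <- match.arg(boundary)
  stopifnot(length(x) == length(values), length(x) >= 3)
  dx <- diff(x[1:2])
  if (max(abs(diff(x) - dx)) > 1e-9 * dx) stop("grid must be regular")
  if (any(values < -1e-12)) stop("density values must be nonnegative")
  structure(list(x = x, values = pmax(values, 0), dx = dx,
                 boundary = boundary, time = time),
            class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf("<density_field: %d cells, dx = %g, %s, t = %g, mass = %g>\n",
              length(x$x), x$dx, x$boundary, x$time, sum(x$values) * x$dx))
  invisible(x)
}

#' Integral of a density field
#' @param field a \code{\link{density_field}}.
#' @return \code{sum(values) * dx}.
#' @export
field_mass <- function(field) sum(field$values) * field$dx

## second difference with boundary handling
lap1d <- function(v, dx, boundary) {
  n <- length(v)
  if (boundary == "periodic") {
    (v[c(2:n, 1)] - 2 * v + v[c(n, 1:(n - 1))]) / dx^2
  } else {
    ## Neumann: ghost cells mirror the boundary values (zero flux)
    (c(v[-1], v[n]) - 2 * v + c(v[1], v[-n])) / dx^2
  }
}

## first-order upwind advection term -b * dv/dx (b scalar)
upwind1d <- function(v, dx, b, boundary) {
  n <- length(v)
  if (b == 0) return(numeric(n))
  if (boundary == "periodic") {
    vm <- v[c(n, 1:(n - 1))]; vp <- v[c(2:n, 1)]
  } else {
    vm <- c(v[1], v[-n]); vp <- c(v[-1], v[n])
  }
  if (b > 0) -b * (v - vm) / dx else -b * (vp - v) / dx
}

traj_new <- function(x, dx, boundary) {
  e <- new.env(parent = emptyenv())
  e$times <- numeric(0); e$values <- list()
  e$x <- x; e$dx <- dx; e$boundary <- boundary
  e$clipped <- 0
  e
}

traj_record <- function(e, t, v) {
  e$times <- c(e$times, t)
  e$values[[length(e$values) + 1L]] <- v
  invisible(e)
}

traj_finish <- function(e) {
  structure(list(times = e$times, values = e$values, x = e$x, dx = e$dx,
                 boundary = e$boundary, clipped_mass = e$clipped),
            class = "field_trajectory")
}

#' @export
print.field_trajectory <- function(x, ...) {
  cat(sprintf("<field_trajectory: %d snapshots, t in [%g, %g], %d cells>\n",
              length(x$times), min(x$times), max(x$times), length(x$x)))
  invisible(x)
}

#' Extract a snapshot from a trajectory
#' @param traj a \code{field_trajectory}.
#' @param i snapshot index (default: last).
#' @return a \code{\link{density_field}}.
#' @export
snapshot_field <- function(traj, i = length(traj$times)) {
  density_field(traj$x, traj$values[[i]], boundary = traj$boundary,
                time = traj$times[i])
}

clip_negative <- function(e, v) {
  neg <- v < 0
  if (any(neg)) {
    e$clipped <- e$clipped + sum(-v[neg]) * e$dx
    v[neg] <- 0
  }
  v
}

#' Solve a classical (local) reaction-diffusion equation
#'
#' Integrates \eqn{\partial_t\phi = (\sigma^2/2)\Delta\phi - b\,\partial_x\phi
#' + \phi F(\phi)} by the method of lines: second-order central differences
#' for the diffusion, first-order upwinding for the drift, explicit Heun
#' time stepping.  With \eqn{\sigma^2 = 2}, \eqn{b = 0} and logistic
#' \eqn{F(m) = 1 - m} this is the Fisher-KPP equation.
#'
#' @param phi0 a \code{\link{density_field}} initial condition.
#' @param F_fn a \code{\link{rate_fn}} or function \code{F(x, m)}.
#' @param sigma2 dispersal variance (diffusion operator \eqn{(\sigma^2/2)\Delta}).
#' @param b constant drift.
#' @param T time horizon.
#' @param dt time step; must satisfy the stability bound
#'   \eqn{\sigma^2 dt/dx^2 \le 0.4}.
#' @param record_every snapshot interval (default: 50 snapshots).
#' @return a \code{field_trajectory}.
#' @export
solve_local_rd <- function(phi0, F_fn, sigma2 = 2, b = 0, T, dt,
                           record_every = T / 50) {
  stopifnot(inherits(phi0, "density_field"))
  dx <- phi0$dx
  if (sigma2 * dt / dx^2 > 0.4 + 1e-12)
    stop(sprintf("CFL violation: sigma2*dt/dx^2 = %.3f > 0.4; use dt <= %g",
                 sigma2 * dt / dx^2, 0.4 * dx^2 / sigma2))
  if (!is.function(F_fn)) F_fn <- rate_fn(F_fn)
  xg <- phi0$x; bc <- phi0$boundary
  rhs <- function(v) {
    (sigma2 / 2) * lap1d(v, dx, bc) + upwind1d(v, dx, b, bc) + v * F_fn(xg, v)
  }
  v <- phi0$values
  e <- traj_new(xg, dx, bc)
  traj_record(e, phi0$time, v)
  nstep <- ceiling(T / dt)
  rec_stride <- max(1L, round(record_every / dt))
  for (s in seq_len(nstep)) {
    k1 <- rhs(v)
    vs <- v + dt * k1
    v <- v + dt / 2 * (k1 + rhs(vs))
    v <- clip_negative(e, v)
    if (s %% rec_stride == 0L || s == nstep)
      traj_record(e, phi0$time + s * dt, v)
  }
  traj_finish(e)
}

## circular convolution of field values with a kernel sampled on the grid
## (kernel centred at the first cell); returns values of (rho * phi)(x).
fft_convolve <- function(v, khat, dx) {
  Re(stats::fft(stats::fft(v) * khat, inverse = TRUE)) / length(v) * dx
}

#' Solve the nonlocal scaling-limit PDE
#'
#' Integrates \eqn{\partial_t\phi = r(x,\rho_r*\phi)\,\mathcal{B}^*
#' (\gamma(\cdot,\rho_\gamma*\phi)\,\phi) + \phi F(x,\rho_F*\phi)} on a
#' periodic grid, computing the three kernel smoothings by FFT at every
#' step.  With \eqn{r \equiv 1}, \eqn{\gamma(x,m) = m},
#' \eqn{F(m) = 1 - m}, \eqn{\rho_F = \rho_\gamma} and \eqn{\sigma^2 = 2}
#' this is the nonlocal porous-medium equation with logistic growth.
#'
#' @param phi0 a periodic \code{\link{density_field}}.
#' @param dem a \code{\link{demography}} (supplies the rates and kernels).
#' @param disp a \code{\link{dispersal_spec}} (supplies \code{sigma2} and
#'   constant drift; only spatially constant coefficients are supported).
#' @param T time horizon.
#' @param dt time step (checked against a CFL bound with the instantaneous
#'   effective diffusivity).
#' @param record_every snapshot interval.
#' @return a \code{field_trajectory}.
#' @export
solve_nonlocal <- function(phi0, dem, disp, T, dt, record_every = T / 50) {
  stopifnot(inherits(phi0, "density_field"), phi0$boundary == "periodic")
  dx <- phi0$dx; xg <- phi0$x; n <- length(xg)
  L <- n * dx
  sigma2 <- disp$C_fn(0)[1, 1]
  b <- disp$b_fn(0)[1]
  khat <- lapply(dem$kernels, function(k)
    stats::fft(kernel_grid(k, xg, L)))
  gamma_fn <- dem$gamma_fn; r_fn <- dem$r_fn; F_fn <- dem$F_fn
  rhs <- function(v) {
    mg <- fft_convolve(v, khat$gamma, dx)
    mr <- fft_convolve(v, khat$r, dx)
    mF <- fft_convolve(v, khat$F, dx)
    gphi <- gamma_fn(xg, pmax(mg, 0)) * v
    r_fn(xg, pmax(mr, 0)) *
      ((sigma2 / 2) * lap1d(gphi, dx, "periodic") +
         upwind1d(gphi, dx, b, "periodic")) +
      v * F_fn(xg, mF)
  }
  ## CFL with effective diffusivity max r * d(m gamma(m))/dm at current state
  cfl_check <- function(v) {
    mg <- pmax(fft_convolve(v, khat$gamma, dx), 0)
    mr <- pmax(fft_convolve(v, khat$r, dx), 0)
    h <- 1e-6
    geff <- pmax(gamma_fn(xg, mg),
                 abs((mg + h) * gamma_fn(xg, mg + h) -
                       (mg - h) * gamma_fn(xg, pmax(mg - h, 0))) / (2 * h))
    Deff <- sigma2 * max(r_fn(xg, mr) * geff)
    if (Deff * dt / dx^2 > 0.4 + 1e-9)
      stop(sprintf(
        "CFL violation: effective sigma2*r*gamma' dt/dx^2 = %.3f > 0.4; use dt <= %g",
        Deff * dt / dx^2, 0.4 * dx^2 / Deff))
  }
  v <- phi0$values
  cfl_check(v)
  e <- traj_new(xg, dx, "periodic")
  traj_record(e, phi0$time, v)
  nstep <- ceiling(T / dt)
  rec_stride <- max(1L, round(record_every / dt))
  check_stride <- max(1L, round(nstep / 20))
  for (s in seq_len(nstep)) {
    k1 <- rhs(v)
    vs <- clip_negative(e, v + dt * k1)
    v <- v + dt / 2 * (k1 + rhs(vs))
    v <- clip_negative(e, v)
    if (s %% check_stride == 0L) cfl_check(v)
    if (s %% rec_stride == 0L || s == nstep)
      traj_record(e, phi0$time + s * dt, v)
  }
  traj_finish(e)
}

#' Solve the porous-medium equation with logistic growth
#'
#' Integrates \eqn{\partial_t\phi = \Delta(\phi^2) + \phi(1-\phi)} with a
#' central-difference Laplacian applied to \eqn{\phi^2} and explicit Euler
#' steps whose size adapts to the degenerate diffusivity:
#' \eqn{dt \le 0.2\,dx^2 / \max(2\phi)} (floored below to keep runs finite).
#'
#' @param phi0 a \code{\link{density_field}}.
#' @param T time horizon.
#' @param dt maximal time step; the solver may take smaller (adaptive) steps.
#' @param record_every snapshot interval.
#' @return a \code{field_trajectory}.
#' @export
solve_pme_logistic <- function(phi0, T, dt = NULL, record_every = T / 50) {
  stopifnot(inherits(phi0, "density_field"))
  dx <- phi0$dx; bc <- phi0$boundary; xg <- phi0$x
  v <- phi0$values
  e <- traj_new(xg, dx, bc)
  traj_record(e, phi0$time, v)
  t <- 0
  next_rec <- record_every
  while (t < T - 1e-12) {
    dt_stab <- 0.2 * dx^2 / max(2 * max(v), 1e-8)
    h <- min(dt_stab, if (is.null(dt)) Inf else dt, T - t, next_rec - t)
    v <- v + h * (lap1d(v^2, dx, bc) + v * (1 - v))
    v <- clip_negative(e, v)
    t <- t + h
    if (t >= next_rec - 1e-12 || t >= T - 1e-12) {
      traj_record(e, phi0$time + t, v)
      if (t >= next_rec - 1e-12) next_rec <- next_rec + record_every
    }
  }
  traj_finish(e)
}

#' Front position of a 1-d density field
#'
#' The rightmost linearly interpolated downcrossing of \code{level}.
#'
#' @param field a \code{\link{density_field}} (or a list with \code{x},
#'   \code{values}).
#' @param level crossing level (default 0.5).
#' @return the front coordinate.
#' @export
front_position <- function(field, level = 0.5) {
  x <- field$x; v <- field$values
  above <- v >= level
  idx <- which(above[-length(v)] & !above[-1])
  if (length(idx) == 0L)
    stop(sprintf("front not found: field never crosses level %g", level))
  i <- max(idx)
  x[i] + (v[i] - level) / (v[i] - v[i + 1]) * (x[i + 1] - x[i])
}

#' Support edge of a field
#'
#' Rightmost point where the density exceeds a small threshold; reported
#' alongside the 0.5-level front for sharp-fronted (porous-medium) waves.
#'
#' @param field a \code{\link{density_field}}.
#' @param threshold support threshold.
#' @return coordinate of the rightmost cell above threshold.
#' @export
support_edge <- function(field, threshold = 1e-6) {
  idx <- which(field$values > threshold)
  if (length(idx) == 0L) stop("field has empty support at this threshold")
  field$x[max(idx)]
}

#' Estimate a front speed from a trajectory
#'
#' Ordinary least-squares slope of the front position against time over a
#' window.
#'
#' @param traj a \code{field_trajectory}.
#' @param level front level passed to \code{\link{front_position}}.
#' @param t_window numeric length-2 window \code{c(a, b)}; snapshots with
#'   \code{a <= t <= b} are used (at least 10 required).
#' @return a list with \code{speed} (the slope), \code{se} (residual standard
#'   error of the slope) and the fitted \code{front} positions and
#'   \code{times}.
#' @export
estimate_speed <- function(traj, level = 0.5, t_window = range(traj$times)) {
  sel <- which(traj$times >= t_window[1] - 1e-9 &
                 traj$times <= t_window[2] + 1e-9)
  if (length(sel) < 10L)
    stop("need at least 10 snapshots inside the window to estimate a speed")
  fr <- vapply(sel, function(i)
    front_position(snapshot_field(traj, i), level), 0)
  tt <- traj$times[sel]
  fit <- stats::lm(fr ~ tt)
  res <- stats::residuals(fit)
  sxx <- sum((tt - mean(tt))^2)
  se <- sqrt(sum(res^2) / (length(tt) - 2) / sxx)
  list(speed = unname(stats::coef(fit)[2]), se = se, front = fr, times = tt)
}
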