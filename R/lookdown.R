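#' Lookdown state
#'
#' The population with auxiliary levels.  In \code{finite_N} mode each
#' individual carries a level in \eqn{[0, N]}; conditionally on the spatial
#' configuration, levels are i.i.d. Uniform[0, N], and an individual dies
#' when its level crosses \eqn{N}.  In \code{limit} mode (the infinite-density
#' limit with \eqn{\alpha = \theta/N}) levels live on \eqn{[0,\infty)},
#' conditionally Poisson given the spatial intensity, and are truncated at
#' \code{u_max} for simulation.  Ignoring levels and assigning mass
#' \eqn{1/N} (resp. \eqn{1/u_{max}}) per individual recovers the population
#' model.
#'
#' @param positions atom locations (1-d numeric vector).
#' @param mode \code{"finite_N"} or \code{"limit"}.
#' @param N density scale (finite_N mode).
#' @param alpha branching intensity \eqn{\theta/N} (limit mode).
#' @param u_max level truncation (limit mode).
#' @param levels optional explicit levels; by default Uniform[0, N] in
#'   finite_N mode and Uniform[0, u_max] thinned from the Poisson structure in
#'   limit mode (supply \code{positions} at the desired spatial intensity).
#' @param domain a \code{\link{domain_spec}}.
#' @param time initial time.
#' @return an object of class \code{lookdown_state}.
#' @export
lookdown_state <- function(positions, mode = c("finite_N", "limit"),
                           N = NULL, alpha = NULL, u_max = NULL,
                           levels = NULL, domain, time = 0) {
  mode <- match.arg(mode)
  positions <- as.numeric(wrap_positions(positions, domain))
  n <- length(positions)
  if (mode == "finite_N") {
    stopifnot(!is.null(N), N > 0)
    if (is.null(levels)) levels <- stats::runif(n, 0, N)
    cap <- N
  } else {
    stopifnot(!is.null(alpha) || TRUE, !is.null(u_max), u_max > 0)
    if (is.null(alpha)) alpha <- 0
    if (is.null(levels)) levels <- stats::runif(n, 0, u_max)
    cap <- u_max
  }
  if (any(levels < 0 | levels >= cap))
    stop("levels must lie in [0, cap)")
  structure(list(positions = positions, levels = levels,
                 labels = as.character(seq_len(n)),
                 mode = mode, N = N, alpha = alpha, u_max = u_max,
                 domain = domain, time = time),
            class = "lookdown_state")
}

#' @export
print.lookdown_state <- function(x, ...) {
  cat(sprintf("<lookdown_state: %s, n = %d, t = %g>\n",
              x$mode, length(x$positions), x$time))
  invisible(x)
}

#' Project a lookdown state to a point population
#'
#' Drops the levels and assigns mass \code{1/N} (finite_N mode) or
#' \code{1/u_max} (limit mode) to each alive individual.
#'
#' @param state a \code{\link{lookdown_state}}.
#' @return a \code{\link{point_population}}.
#' @export
project <- function(state) {
  stopifnot(inherits(state, "lookdown_state"))
  Nproj <- if (state$mode == "finite_N") state$N else state$u_max
  point_population(state$positions, Nproj, state$domain, time = state$time)
}

#' Level-ODE coefficients at a location
#'
#' Between reproduction events the level \eqn{u} of an individual at \eqn{x}
#' satisfies \eqn{\dot u = c\,u^2 - b\,u} with
#' \deqn{c = (\theta/N)\,\gamma(x,\eta)\int r(y,\eta)\,q_\theta(x,dy), \quad
#'       b = \theta\gamma(x,\eta)\int (r(y,\eta)-r(x,\eta))\,q_\theta(x,dy)
#'           + F(x,\eta).}
#' The dispersal integrals are computed by Gauss-Hermite quadrature
#' (\code{M} nodes); when \eqn{r} is a registered constant they collapse
#' exactly (and then \eqn{b = F(x,\eta)}).
#'
#' @param x query location(s).
#' @param pop the current \code{\link{point_population}} (defines \eqn{\eta}).
#' @param dem a \code{\link{demography}}.
#' @param disp a \code{\link{dispersal_spec}}.
#' @param M quadrature nodes per axis.
#' @return list with vectors \code{b_level} and \code{c_level}.
#' @export
level_coeffs <- function(x, pop, dem, disp, M = 20L) {
  x <- as.numeric(x)
  m_g <- local_density(pop, dem$kernels$gamma, x)
  m_F <- local_density(pop, dem$kernels$F, x)
  gam <- dem$gamma_fn(x, m_g)
  Fv <- dem$F_fn(x, m_F)
  if (rate_is_constant(dem$r_fn)) {
    r0 <- dem$r_fn(0, 0)
    I <- rep(r0, length(x))
    r_self <- I
  } else {
    m_r <- local_density(pop, dem$kernels$r, x)
    r_self <- dem$r_fn(x, m_r)
    gh <- gh_rule(M)
    th <- disp$theta
    I <- vapply(x, function(xi) {
      mu <- xi + disp$b_fn(xi)[1] / th
      sd <- sqrt(disp$C_fn(xi)[1, 1] / th)
      y <- mu + sd * gh$t
      sum(gh$w * dem$r_fn(y, local_density(pop, dem$kernels$r, y)))
    }, 0)
  }
  list(b_level = dem$theta * gam * (I - r_self) + Fv,
       c_level = (dem$theta / dem$N) * gam * I)
}

#' Evolve a level under the quadratic level ODE
#'
#' Closed-form solution of \eqn{\dot u = c u^2 - b u} with frozen
#' coefficients: in the reciprocal coordinate \eqn{v = 1/u},
#' \eqn{v(t) = c/b + (1/u_0 - c/b)e^{bt}} for \eqn{b \ne 0} and
#' \eqn{v(t) = 1/u_0 - ct} for \eqn{b = 0}.  If \eqn{v} reaches 0 within the
#' step the level escapes to \eqn{+\infty} and the escape time is reported.
#'
#' @param u0 initial level(s), positive.
#' @param b,c ODE coefficients (\code{c} nonnegative); vectorised.
#' @param dt step length.
#' @return list with \code{u} (level at \code{dt}, possibly \code{Inf}) and
#'   \code{escape_time} (\code{NA} if no escape within the step).
#' @export
evolve_level <- function(u0, b, c, dt) {
  k <- max(length(u0), length(b), length(c))
  u0 <- rep_len(u0, k); b <- rep_len(b, k); c <- rep_len(c, k)
  stopifnot(all(u0 > 0), all(c >= 0), dt >= 0)
  v0 <- 1 / u0
  v <- numeric(k); tesc <- rep(NA_real_, k)
  zb <- b == 0
  v[zb] <- v0[zb] - c[zb] * dt
  nz <- !zb
  v[nz] <- c[nz] / b[nz] + (v0[nz] - c[nz] / b[nz]) * exp(b[nz] * dt)
  esc <- v <= 0
  if (any(esc)) {
    i <- which(esc & zb)
    tesc[i] <- v0[i] / c[i]
    i <- which(esc & nz)
    tesc[i] <- log(c[i] / (c[i] - b[i] * v0[i])) / b[i]
  }
  list(u = ifelse(esc, Inf, 1 / v), escape_time = tesc)
}

## first time v = 1/u falls to 1/u_cap (level crosses u_cap); Inf if never
level_hit_time <- function(u0, b, c, u_cap) {
  k <- max(length(u0), length(b), length(c))
  u0 <- rep_len(u0, k); b <- rep_len(b, k); c <- rep_len(c, k)
  vT <- 1 / u_cap
  v0 <- 1 / u0
  out <- rep(Inf, k)
  zb <- b == 0
  i <- which(zb & c > 0 & v0 > vT)
  out[i] <- (v0[i] - vT) / c[i]
  i <- which(!zb)
  if (length(i)) {
    A <- v0[i] - c[i] / b[i]
    q <- (vT - c[i] / b[i]) / A
    ok <- A != 0 & q > 0
    t1 <- rep(Inf, length(i))
    t1[ok] <- log(q[ok]) / b[i][ok]
    t1[!is.finite(t1) | t1 <= 0] <- Inf
    out[i] <- t1
  }
  out
}

## --- event log helpers -----------------------------------------------------

log_new <- function() {
  e <- new.env(parent = emptyenv())
  e$rows <- list()
  e
}

log_add <- function(e, time, type, parent_label, child_label = NA_character_,
                    x_parent = NA_real_, x_child = NA_real_,
                    u_new = NA_real_, kappa = NA_integer_) {
  e$rows[[length(e$rows) + 1L]] <-
    list(time = time, type = type, parent_label = parent_label,
         child_label = child_label, x_parent = x_parent, x_child = x_child,
         u_new = u_new, kappa = kappa)
  invisible(e)
}

log_df <- function(e) {
  if (length(e$rows) == 0L)
    return(data.frame(time = numeric(0), type = character(0),
                      parent_label = character(0), child_label = character(0),
                      x_parent = numeric(0), x_child = numeric(0),
                      u_new = numeric(0), kappa = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind.data.frame, c(e$rows, list(stringsAsFactors = FALSE)))
}

#' Run the lookdown process
#'
#' \strong{finite_N mode}: between events, levels follow the closed-form
#' solution of \eqn{\dot u = c u^2 - b u} with coefficients refreshed at each
#' event (positions are fixed between events, so the coefficients are exact
#' per piece).  Each individual proposes births at the bound
#' \eqn{2\theta\gamma(x,\eta)} and accepts with probability \eqn{1 - u/N}
#' (exact thinning); an accepted juvenile at \eqn{y} establishes with
#' probability \eqn{r(y,\eta)} on the pre-birth population, receives a level
#' \eqn{u_1 \sim U[u, N]}, and a fair coin \eqn{\kappa} decides whether the
#' parent or the offspring takes the new level (the line of descent keeps the
#' old level; the new label goes with the new level).  Levels crossing
#' \eqn{N} are deaths.
#'
#' \strong{limit mode}: lines of descent move as diffusions with drift
#' \eqn{\beta = r\gamma(b + C\,\partial_x \log r)} and squared diffusion
#' \eqn{r\gamma C}; levels follow \eqn{\dot u = \alpha\gamma r u^2 -
#' (\gamma\mathcal{B}r + F)u}; new lines appear above level \eqn{u} as a
#' Poisson process with intensity \eqn{2\alpha\gamma r} per unit level,
#' truncated at \code{u_max}.  With \eqn{\alpha = 0} no new lines are ever
#' created.
#'
#' @param state0 a \code{\link{lookdown_state}}.
#' @param dem a \code{\link{demography}} (its \code{theta}, \code{N} are used
#'   in finite_N mode; its rates and kernels in both).
#' @param disp a \code{\link{dispersal_spec}}.
#' @param T scaled-time horizon.
#' @param record_every summary recording interval.
#' @param dt_max maximal coefficient-freeze interval (limit mode Euler step;
#'   finite_N coefficient refreshes are event-driven and exact).
#' @param n_max explosion guard.
#' @return an object of class \code{lookdown_run}: final \code{state}, the
#'   \code{events} data frame, founder table, and recorded \code{times} /
#'   \code{mass}.
#' @export
lookdown_run <- function(state0, dem, disp, T, record_every = T / 20,
                         dt_max = 0.01, n_max = NULL) {
  stopifnot(inherits(state0, "lookdown_state"))
  founders <- data.frame(label = state0$labels, x0 = state0$positions,
                         stringsAsFactors = FALSE)
  if (state0$mode == "finite_N")
    run_lookdown_finiteN(state0, dem, disp, T, record_every, n_max, founders)
  else
    run_lookdown_limit(state0, dem, disp, T, record_every, dt_max, n_max,
                       founders)
}

run_lookdown_finiteN <- function(state0, dem, disp, T, record_every, n_max,
                                 founders) {
  domain <- state0$domain
  N <- state0$N
  theta <- dem$theta
  if (is.null(n_max)) n_max <- ceiling(100 * N * prod(domain$lengths))
  pos <- state0$positions; lev <- state0$levels; lab <- state0$labels
  child_count <- new.env(parent = emptyenv())
  ev <- log_new()
  t <- state0$time; t_end <- t + T; next_rec <- t
  rec_t <- numeric(0); rec_m <- numeric(0)
  coeffs <- NULL
  r_const <- rate_is_constant(dem$r_fn)
  refresh <- function() {
    pop <- point_population(pos, N, domain, time = t)
    dens <- atom_densities_direct(pop, dem$kernels)
    gam <- dem$gamma_fn(pos, dens$gamma)
    Fv <- dem$F_fn(pos, dens$F)
    if (r_const) {
      I <- dem$r_fn(0, 0)
      b <- Fv
      cc <- (theta / N) * gam * I
    } else {
      cf <- level_coeffs(pos, pop, dem, disp)
      b <- cf$b_level; cc <- cf$c_level
    }
    list(b = b, c = cc, gam = gam, pop = pop)
  }
  new_label <- function(parent) {
    k <- (if (is.null(child_count[[parent]])) 0L else child_count[[parent]]) + 1L
    child_count[[parent]] <- k
    paste0(parent, ".", k)
  }
  dirty <- TRUE
  while (t < t_end - 1e-12) {
    n <- length(pos)
    while (next_rec <= t + 1e-12 && next_rec <= t_end + 1e-12) {
      rec_t <- c(rec_t, next_rec); rec_m <- c(rec_m, n / N)
      next_rec <- next_rec + record_every
    }
    if (n == 0L) { t <- t_end; break }
    if (n > n_max) stop("lookdown population exploded past n_max")
    if (dirty) { coeffs <- refresh(); dirty <- FALSE }
    t_hit <- level_hit_time(lev, coeffs$b, coeffs$c, N)
    te <- min(t_hit)
    Lam <- 2 * theta * sum(coeffs$gam)
    tau <- if (Lam > 0) stats::rexp(1, Lam) else Inf
    step <- min(tau, te, t_end - t, next_rec - t)
    lev <- evolve_level(lev, coeffs$b, coeffs$c, step)$u
    t <- t + step
    if (te <= step + 1e-14 && te <= tau) {
      dead <- which(!is.finite(lev) | lev >= N * (1 - 1e-12))
      if (length(dead) == 0L) dead <- which.min(N - lev)
      for (i in dead)
        log_add(ev, t, "death", lab[i], x_parent = pos[i])
      keep <- setdiff(seq_along(pos), dead)
      pos <- pos[keep]; lev <- lev[keep]; lab <- lab[keep]
      dirty <- TRUE
      next
    }
    if (is.finite(tau) && step == tau) {
      i <- sample.int(n, 1L, prob = coeffs$gam)
      if (stats::runif(1) < max(0, 1 - lev[i] / N)) {
        y <- sample_dispersal(disp, pos[i], domain)
        m_r_y <- local_density(coeffs$pop, dem$kernels$r, y)
        if (stats::runif(1) < dem$r_fn(y, m_r_y)) {
          u1 <- stats::runif(1, lev[i], N)
          kappa <- stats::rbinom(1, 1, 0.5)
          chl <- new_label(lab[i])
          x_par <- pos[i]
          log_add(ev, t, "birth", parent_label = lab[i], child_label = chl,
                  x_parent = x_par, x_child = y, u_new = u1, kappa = kappa)
          if (kappa == 0L) {
            ## offspring takes the new level and the new label
            pos <- c(pos, y); lev <- c(lev, u1); lab <- c(lab, chl)
          } else {
            ## parent individual takes the new level and the new label;
            ## the line of descent (old label, old level) continues in the
            ## offspring at y
            pos <- c(pos, x_par); lev <- c(lev, u1); lab <- c(lab, chl)
            pos[i] <- y
          }
          dirty <- TRUE
        }
      }
    }
  }
  while (next_rec <= t_end + 1e-12) {
    rec_t <- c(rec_t, next_rec); rec_m <- c(rec_m, length(pos) / N)
    next_rec <- next_rec + record_every
  }
  state <- structure(list(positions = pos, levels = lev, labels = lab,
                          mode = "finite_N", N = N, alpha = dem$alpha,
                          u_max = NULL, domain = domain, time = t_end),
                     class = "lookdown_state")
  structure(list(state = state, events = log_df(ev), founders = founders,
                 times = rec_t, mass = rec_m, T = t_end),
            class = "lookdown_run")
}

run_lookdown_limit <- function(state0, dem, disp, T, record_every, dt_max,
                               n_max, founders) {
  domain <- state0$domain
  u_max <- state0$u_max
  alpha <- if (!is.null(state0$alpha)) state0$alpha else dem$alpha
  if (is.null(n_max)) n_max <- ceiling(100 * u_max * prod(domain$lengths))
  pos <- state0$positions; lev <- state0$levels; lab <- state0$labels
  child_count <- new.env(parent = emptyenv())
  ev <- log_new()
  t <- state0$time; t_end <- t + T; next_rec <- t
  rec_t <- numeric(0); rec_m <- numeric(0)
  h <- 1e-4
  new_label <- function(parent) {
    k <- (if (is.null(child_count[[parent]])) 0L else child_count[[parent]]) + 1L
    child_count[[parent]] <- k
    paste0(parent, ".", k)
  }
  sigma2 <- disp$C_fn(0)[1, 1]
  bdrift <- disp$b_fn(0)[1]
  while (t < t_end - 1e-12) {
    n <- length(pos)
    while (next_rec <= t + 1e-12 && next_rec <= t_end + 1e-12) {
      rec_t <- c(rec_t, next_rec); rec_m <- c(rec_m, n / u_max)
      next_rec <- next_rec + record_every
    }
    if (n == 0L) break
    if (n > n_max) stop("lookdown population exploded past n_max")
    dt <- min(dt_max, t_end - t, next_rec - t + record_every)
    pop <- point_population(pos, u_max, domain, time = t)
    m_g <- local_density(pop, dem$kernels$gamma, pos)
    m_F <- local_density(pop, dem$kernels$F, pos)
    gam <- dem$gamma_fn(pos, m_g)
    Fv <- dem$F_fn(pos, m_F)
    r_at <- function(xq) dem$r_fn(xq, local_density(pop, dem$kernels$r, xq))
    r0 <- r_at(pos)
    rp <- (r_at(pos + h) - r_at(pos - h)) / (2 * h)
    rpp <- (r_at(pos + h) - 2 * r0 + r_at(pos - h)) / h^2
    Br <- (sigma2 / 2) * rpp + bdrift * rp
    beta <- r0 * gam * (bdrift + sigma2 * rp / pmax(r0, 1e-12))
    Jdiff <- sqrt(pmax(r0 * gam * sigma2, 0))
    ## levels: du/dt = alpha*gam*r*u^2 - (gam*Br + F)*u, frozen over dt
    c_lim <- alpha * gam * r0
    b_lim <- gam * Br + Fv
    t_hit <- level_hit_time(lev, b_lim, c_lim, u_max)
    lev <- evolve_level(lev, b_lim, c_lim, dt)$u
    ## new lines of descent (Poisson, intensity 2*alpha*gam*r per unit level)
    if (alpha > 0) {
      rate <- 2 * alpha * gam * r0 * pmax(u_max - lev, 0) * dt
      rate[!is.finite(lev)] <- 0
      k_new <- stats::rpois(n, rate)
      for (i in which(k_new > 0)) {
        for (j in seq_len(k_new[i])) {
          u1 <- stats::runif(1, lev[i], u_max)
          chl <- new_label(lab[i])
          pos <- c(pos, pos[i]); lev <- c(lev, u1); lab <- c(lab, chl)
          log_add(ev, t + dt, "birth", lab[i], chl,
                  x_parent = pos[i], x_child = pos[i], u_new = u1, kappa = NA)
        }
      }
    }
    ## spatial diffusion of the original n lines
    idx <- seq_len(n)
    pos[idx] <- wrap_positions(
      pos[idx] + beta * dt + Jdiff * sqrt(dt) * stats::rnorm(n), domain)
    ## deaths at the truncation
    dead <- which(!is.finite(lev) | lev >= u_max)
    if (length(dead)) {
      for (i in dead) log_add(ev, t + dt, "death", lab[i], x_parent = pos[i])
      keep <- setdiff(seq_along(pos), dead)
      pos <- pos[keep]; lev <- lev[keep]; lab <- lab[keep]
    }
    t <- t + dt
  }
  while (next_rec <= t_end + 1e-12) {
    rec_t <- c(rec_t, next_rec); rec_m <- c(rec_m, length(pos) / u_max)
    next_rec <- next_rec + record_every
  }
  state <- structure(list(positions = pos, levels = lev, labels = lab,
                          mode = "limit", N = NULL, alpha = alpha,
                          u_max = u_max, domain = domain, time = t_end),
                     class = "lookdown_state")
  structure(list(state = state, events = log_df(ev), founders = founders,
                 times = rec_t, mass = rec_m, T = t_end),
            class = "lookdown_run")
}

#' @export
print.lookdown_run <- function(x, ...) {
  cat(sprintf("<lookdown_run: %s, %d events, final n = %d, T = %g>\n",
              x$state$mode, nrow(x$events), length(x$state$positions), x$T))
  invisible(x)
}

#' Sample the k lowest levels in a region
#'
#' By the exchangeability of levels, the \code{k} individuals with the lowest
#' levels in a region form a uniform random sample of size \code{k} from the
#' population of that region.
#'
#' @param state a \code{\link{lookdown_state}}.
#' @param region numeric length-2 interval \code{c(lo, hi)}.
#' @param k sample size.
#' @return data frame (label, position, level) ordered by level.
#' @export
sample_k_lowest <- function(state, region, k) {
  inb <- which(state$positions >= region[1] & state$positions <= region[2])
  if (length(inb) < k)
    stop(sprintf("region holds %d individuals, fewer than k = %d",
                 length(inb), k))
  ord <- inb[order(state$levels[inb])][seq_len(k)]
  data.frame(label = state$labels[ord], position = state$positions[ord],
             level = state$levels[ord], stringsAsFactors = FALSE)
}

## ancestor label of `lab` alive at time t (prefix resolution), plus the
## birth times of every prefix, from the run's event log
label_birth_time <- function(run, lab) {
  if (lab %in% run$founders$label) return(0)
  i <- match(lab, run$events$child_label)
  if (is.na(i)) stop("unknown label: ", lab)
  run$events$time[i]
}

label_parent <- function(lab) {
  parts <- strsplit(lab, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1L) NA_character_ else
    paste(parts[-length(parts)], collapse = ".")
}

## position timeline of a single label over its lifetime: times at which the
## label's position changed (creation + kappa=1 events where it was parent)
label_position_timeline <- function(run, lab) {
  ev <- run$events
  if (lab %in% run$founders$label) {
    t0 <- 0
    x0 <- run$founders$x0[match(lab, run$founders$label)]
  } else {
    i <- match(lab, ev$child_label)
    if (is.na(i)) stop("unknown label: ", lab)
    t0 <- ev$time[i]
    ## kappa = 0: child label starts at the offspring location;
    ## kappa = 1: the new label is taken by the parent individual (stays put)
    x0 <- if (!is.na(ev$kappa[i]) && ev$kappa[i] == 1L) ev$x_parent[i] else
      ev$x_child[i]
  }
  jumps <- which(ev$type == "birth" & ev$parent_label == lab &
                   !is.na(ev$kappa) & ev$kappa == 1L)
  data.frame(time = c(t0, ev$time[jumps]),
             position = c(x0, ev$x_child[jumps]))
}

#' Trace an ancestral lineage backward in time
#'
#' Walks the Ulam-Harris ancestry of a sampled individual's label through the
#' event log.  Because the line of descent keeps the lower level at each
#' birth, following the label backward (jumping to the parent's location
#' exactly when the sampled line received the offspring role, i.e. at
#' \eqn{\kappa = 1} events on its own label and at its creation when
#' \eqn{\kappa = 0}) yields the pedigree ancestor positions.
#'
#' @param run a \code{\link{lookdown_run}}.
#' @param label the sampled individual's label at the reference time.
#' @param s backward horizon (in \eqn{[0, T]}).
#' @param T reference (sampling) time; defaults to the run end.
#' @return a data frame with backward time \code{s}, forward \code{time} and
#'   ancestor \code{position}, ordered by increasing \code{s} (piecewise
#'   constant between rows).
#' @export
trace_lineage <- function(run, label, s, T = run$T) {
  stopifnot(inherits(run, "lookdown_run"), s >= 0, s <= T + 1e-12)
  t_stop <- T - s
  lab <- label
  rows <- list()
  t_cur <- T
  repeat {
    tl <- label_position_timeline(run, lab)
    tl <- tl[tl$time <= t_cur + 1e-12, , drop = FALSE]
    for (j in rev(seq_len(nrow(tl)))) {
      rows[[length(rows) + 1L]] <- list(time = min(t_cur, run$T),
                                        position = tl$position[j])
      t_cur <- tl$time[j]
      if (t_cur <= t_stop) break
    }
    if (t_cur <= t_stop) break
    if (lab %in% run$founders$label) break
    lab <- label_parent(lab)
    if (is.na(lab)) break
  }
  tt <- vapply(rows, `[[`, 0, "time")
  xx <- vapply(rows, `[[`, 0, "position")
  ord <- order(tt, decreasing = TRUE)
  data.frame(s = T - tt[ord], time = tt[ord], position = xx[ord])
}

#' Export sampled genealogies as Newick trees
#'
#' Builds the ancestry forest of a set of sampled labels back to time 0,
#' merging lineages at shared birth events.  Branch lengths are in scaled
#' time; leaves are label strings (dots replaced by underscores); one Newick
#' string per founder subtree represented in the sample.
#'
#' @param run a \code{\link{lookdown_run}}.
#' @param labels sampled labels (alive at \code{T}).
#' @param T sampling time (default: run end).
#' @return character vector of Newick strings.
#' @export
export_genealogy <- function(run, labels, T = run$T) {
  stopifnot(all(labels %in% run$state$labels))
  chains <- lapply(labels, function(l) {
    ch <- l
    while (!ch[1] %in% run$founders$label) ch <- c(label_parent(ch[1]), ch)
    ch
  })
  chain_labels <- unique(unlist(chains))
  sampled <- labels
  leafname <- function(l) gsub(".", "_", l, fixed = TRUE)
  ## node(L, t_from) -> list(str, time): subtree rooted where label L exists
  ## at t_from; str has no branch length above its root
  node <- function(L, t_from) {
    ev <- run$events
    kids <- which(ev$type == "birth" & ev$parent_label == L &
                    ev$child_label %in% chain_labels &
                    ev$time >= t_from - 1e-12)
    kids <- kids[order(ev$time[kids])]
    build <- function(ki) {
      if (length(ki) == 0L) {
        if (!L %in% sampled)
          stop("internal genealogy error: chain label without sampled tip")
        return(list(str = leafname(L), time = T))
      }
      i <- ki[1]
      tb <- ev$time[i]
      right <- node(ev$child_label[i], tb)
      if (length(ki) == 1L && !L %in% sampled) {
        ## pass-through: the event is not a coalescence within the sample
        return(right)
      }
      left <- build(ki[-1])
      list(str = sprintf("(%s:%.12g,%s:%.12g)",
                         left$str, left$time - tb,
                         right$str, right$time - tb),
           time = tb)
    }
    build(kids)
  }
  roots <- unique(vapply(chains, `[[`, "", 1L))
  unname(vapply(roots, function(R) {
    nd <- node(R, 0)
    sprintf("(%s:%.12g);", nd$str, nd$time)
  }, ""))
}
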