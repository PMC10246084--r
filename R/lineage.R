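#' Stationary lab-frame source for lineage coefficients
#'
#' Describes a stationary population profile and the demographic rates as
#' functions of location only (their density arguments already evaluated at
#' the stationary profile), for use with \code{\link{lineage_coeffs}}.
#'
#' @param phi_fn stationary density profile, a function of x (or a constant).
#' @param r_fn,gamma_fn establishment and birth rates as functions of x at
#'   stationarity (constants allowed).
#' @param sigma2 dispersal variance (\eqn{C = \sigma^2}).
#' @param b constant drift (must be a gradient; 0 in all shipped examples).
#' @param period optional spatial period for periodic sources.
#' @return an object of class \code{stationary_source}.
#' @export
stationary_source <- function(phi_fn, r_fn = 1, gamma_fn = 1, sigma2 = 2,
                              b = 0, period = NULL) {
  as_fn <- function(f) if (is.function(f)) f else {
    v <- as.numeric(f); function(x) rep_len(v, length(x))
  }
  structure(list(phi_fn = as_fn(phi_fn), r_fn = as_fn(r_fn),
                 gamma_fn = as_fn(gamma_fn), sigma2 = sigma2, b = b,
                 period = period),
            class = "stationary_source")
}

#' Ancestral-lineage diffusion coefficients
#'
#' Assembles the generator of the backward-in-time ancestral lineage
#' diffusion \eqn{a(x)\partial_{xx} + \mu(x)\partial_x} (1-d).
#'
#' In the lab frame with isotropic dispersal the generator is
#' \eqn{(\sigma^2/2) r\gamma[\Delta + (2\nabla\log(\gamma\phi) -
#' 2b/\sigma^2)\cdot\nabla]}, so \eqn{a = (\sigma^2/2) r\gamma} and
#' \eqn{\mu = \sigma^2 r\gamma \nabla\log(\gamma\phi) - r\gamma b}.
#' In the frame moving with a travelling wave at speed \eqn{c}
#' (\eqn{\sigma^2 = 2}, \eqn{b = 0}): \eqn{a = r\gamma} and
#' \eqn{\mu = 2r\gamma\,\partial_x \log(\gamma w) + c}.
#' For the porous-medium wave the diffusion coefficient
#' \eqn{a = w = 1 - e^{x/2}} vanishes continuously at the front and the
#' drift tends to \eqn{-1}.
#'
#' @param source a \code{\link{wave_frame_model}} or a
#'   \code{\link{stationary_source}}.
#' @param frame \code{"wave"} or \code{"lab"} (inferred from the source by
#'   default).
#' @param dx finite-difference step for log-gradients where no closed form
#'   exists.
#' @return an object of class \code{lineage_coeffs}: functions \code{a_fn(x)}
#'   and \code{drift_fn(x)}, the \code{frame}, and (for the porous-medium
#'   wave) the degenerate front location.
#' @export
lineage_coeffs <- function(source, frame = NULL, dx = 1e-5) {
  if (inherits(source, "wave_frame_model")) {
    model <- source
    gw <- function(x) {
      w <- wave_profile(model, x)
      if (model$kind == "pme_logistic") w^2 else w
    }
    rg <- function(x) {
      w <- wave_profile(model, x)
      if (model$kind == "pme_logistic") w else rep(1, length(x))
    }
    drift_fn <- function(x) {
      g <- gw(x)
      dlog <- (log(pmax(gw(x + dx), 1e-300)) -
                 log(pmax(gw(x - dx), 1e-300))) / (2 * dx)
      2 * rg(x) * dlog + model$speed
    }
    if (model$kind == "allen_cahn") {
      drift_fn <- function(x) model$s - 2 * exp(x) / (1 + exp(x))
    } else if (model$kind == "pme_logistic") {
      drift_fn <- function(x) 1 - 2 * exp(pmin((x - model$x0) / 2, 0)) *
        (x < model$x0)
      ## drift -> -1 as x -> x0-: 1 - 2 e^{x/2}
      drift_fn <- function(x) ifelse(x < model$x0,
                                     1 - 2 * exp((x - model$x0) / 2), NA_real_)
    }
    a_fn <- function(x) {
      if (model$kind == "pme_logistic")
        ifelse(x < model$x0, 1 - exp((x - model$x0) / 2), 0)
      else rep(1, length(x))
    }
    structure(list(a_fn = a_fn, drift_fn = drift_fn, frame = "wave",
                   model = model,
                   degenerate_at = if (model$kind == "pme_logistic")
                     model$x0 else NULL,
                   period = NULL),
              class = "lineage_coeffs")
  } else if (inherits(source, "stationary_source")) {
    s2 <- source$sigma2
    wrapx <- if (!is.null(source$period)) {
      L <- source$period; function(x) x %% L
    } else identity
    gphi <- function(x) {
      x <- wrapx(x)
      pmax(source$gamma_fn(x) * source$phi_fn(x), 1e-300)
    }
    rg <- function(x) {
      x <- wrapx(x)
      source$r_fn(x) * source$gamma_fn(x)
    }
    a_fn <- function(x) (s2 / 2) * rg(x)
    drift_fn <- function(x) {
      dlog <- (log(gphi(x + dx)) - log(gphi(x - dx))) / (2 * dx)
      rg(x) * (s2 * dlog - source$b)
    }
    structure(list(a_fn = a_fn, drift_fn = drift_fn, frame = "lab",
                   source = source, degenerate_at = NULL,
                   period = source$period),
              class = "lineage_coeffs")
  } else stop("unsupported lineage source")
}

#' @export
print.lineage_coeffs <- function(x, ...) {
  cat(sprintf("<lineage_coeffs: %s frame>\n", x$frame))
  invisible(x)
}

#' Simulate ancestral lineage paths
#'
#' Euler-Maruyama integration of the diffusion \eqn{dX = \mu(X)\,ds +
#' \sqrt{2a(X)}\,dW} in backward time \eqn{s}.  At a degenerate boundary
#' (the porous-medium front, where \eqn{a \to 0}) paths are reflected at a
#' small offset behind the front.
#'
#' @param coeffs a \code{\link{lineage_coeffs}}.
#' @param x0 starting position(s) (recycled over paths).
#' @param S backward-time horizon.
#' @param dt Euler step.
#' @param n_paths number of independent paths.
#' @param record_every interval between recorded positions.
#' @param boundary_offset reflection offset behind a degenerate front.
#' @return an object of class \code{lineage_ensemble}: backward times
#'   \code{s} and a matrix \code{paths} (\code{n_paths} rows).
#' @export
simulate_lineage <- function(coeffs, x0, S, dt = 1e-3, n_paths = 100,
                             record_every = max(dt, S / 200),
                             boundary_offset = 1e-6) {
  stopifnot(inherits(coeffs, "lineage_coeffs"))
  x <- rep_len(x0, n_paths)
  nstep <- ceiling(S / dt)
  stride <- max(1L, round(record_every / dt))
  nrec <- floor(nstep / stride) + 1L
  out <- matrix(NA_real_, n_paths, nrec)
  out[, 1L] <- x
  svec <- numeric(nrec); svec[1L] <- 0
  wall <- if (!is.null(coeffs$degenerate_at))
    coeffs$degenerate_at - boundary_offset else NULL
  j <- 1L
  for (k in seq_len(nstep)) {
    a <- pmax(coeffs$a_fn(x), 0)
    mu <- coeffs$drift_fn(x)
    x <- x + mu * dt + sqrt(2 * a * dt) * stats::rnorm(n_paths)
    if (!is.null(wall)) {
      over <- x > wall
      if (any(over)) x[over] <- 2 * wall - x[over]
    }
    if (!is.null(coeffs$period)) x <- x %% coeffs$period
    if (k %% stride == 0L) {
      j <- j + 1L
      out[, j] <- x
      svec[j] <- k * dt
    }
  }
  structure(list(s = svec[seq_len(j)], paths = out[, seq_len(j), drop = FALSE],
                 frame = coeffs$frame),
            class = "lineage_ensemble")
}

#' @export
print.lineage_ensemble <- function(x, ...) {
  cat(sprintf("<lineage_ensemble: %d paths, S = %g>\n",
              nrow(x$paths), max(x$s)))
  invisible(x)
}

#' Stationary density (speed measure) of a lineage diffusion
#'
#' For a 1-d generator \eqn{a(x)\partial_{xx} + \mu(x)\partial_x} the speed
#' measure has density \eqn{m(x) \propto a(x)^{-1}\exp(\int^x \mu/a)}; when
#' integrable, its normalisation is the unique stationary distribution.
#' Closed forms are returned for the reference waves:
#' Allen-Cahn \eqn{m_A(x) = e^{sx}(1+e^x)^{-2} / B(s, 2-s)};
#' porous-medium \eqn{m_P(\xi) = 3e^{\xi}(1 - e^{\xi/2})} on \eqn{\xi < 0}
#' (the normalising constant is 3 since \eqn{\int_{-\infty}^0
#' e^{\xi}(1-e^{\xi/2})d\xi = 1/3}); Fisher-KPP has a non-integrable speed
#' measure (lineages escape into the tip) and no stationary distribution.
#'
#' @param source a \code{\link{wave_frame_model}}, a
#'   \code{\link{stationary_source}}, or a \code{\link{lineage_coeffs}}.
#' @param grid evaluation grid (required for numeric sources).
#' @return an object of class \code{stationary_density}: \code{x},
#'   \code{density} (normalised if integrable), and \code{integrable}.
#' @export
stationary_density <- function(source, grid = NULL) {
  if (inherits(source, "wave_frame_model")) {
    if (source$kind == "allen_cahn") {
      s <- source$s
      if (is.null(grid)) grid <- seq(-30, 30, length.out = 2001)
      Z <- beta(s, 2 - s)
      dens <- exp(s * grid) / (1 + exp(grid))^2 / Z
      return(structure(list(x = grid, density = dens, integrable = TRUE,
                            normalization = Z, kind = "allen_cahn"),
                       class = "stationary_density"))
    }
    if (source$kind == "pme_logistic") {
      if (is.null(grid)) grid <- seq(-30, 0, length.out = 2001)
      xi <- grid - source$x0
      dens <- ifelse(xi < 0, 3 * exp(xi) * (1 - exp(xi / 2)), 0)
      return(structure(list(x = grid, density = dens, integrable = TRUE,
                            normalization = 1 / 3, kind = "pme_logistic"),
                       class = "stationary_density"))
    }
    ## fisher_kpp: speed density ~ w^2 e^{2x} -> constant in the tip
    return(structure(list(x = grid, density = NULL, integrable = FALSE,
                          kind = "fisher_kpp",
                          reason = "speed measure does not decay in the wave tip"),
                     class = "stationary_density"))
  }
  if (inherits(source, "stationary_source")) {
    ## reversible stationary law pi ~ (gamma/r) phi^2 e^{-2h/sigma2} with
    ## b = grad h (constant b: h = b x)
    stopifnot(!is.null(grid))
    m <- source$gamma_fn(grid) / pmax(source$r_fn(grid), 1e-300) *
      source$phi_fn(grid)^2 *
      exp(-2 * source$b * grid / source$sigma2)
    dxg <- diff(grid)
    Z <- sum((m[-1] + m[-length(m)]) / 2 * dxg)
    integrable <- !is.null(source$period) ||
      max(m[1], m[length(m)]) < 1e-6 * max(m)
    return(structure(list(x = grid,
                          density = if (integrable) m / Z else m,
                          integrable = integrable, normalization = Z,
                          kind = "stationary_lab"),
                     class = "stationary_density"))
  }
  coeffs <- if (inherits(source, "lineage_coeffs")) source else
    lineage_coeffs(source)
  stopifnot(!is.null(grid))
  a <- pmax(coeffs$a_fn(grid), 1e-300)
  mu <- coeffs$drift_fn(grid)
  dxg <- diff(grid)
  ## cumulative trapezoid of mu/a
  integrand <- mu / a
  cumint <- c(0, cumsum((integrand[-1] + integrand[-length(grid)]) / 2 * dxg))
  m <- exp(cumint - max(cumint)) / a
  Z <- sum((m[-1] + m[-length(m)]) / 2 * dxg)
  edge <- max(m[1], m[length(m)])
  integrable <- is.finite(Z) && edge < 1e-6 * max(m)
  structure(list(x = grid,
                 density = if (integrable) m / Z else m,
                 integrable = integrable,
                 normalization = Z, kind = "numeric"),
            class = "stationary_density")
}

#' @export
print.stationary_density <- function(x, ...) {
  if (isTRUE(x$integrable))
    cat(sprintf("<stationary_density: %s, normalised on %d points>\n",
                x$kind, length(x$x)))
  else
    cat(sprintf("<stationary_density: %s, NOT integrable (no stationary distribution)>\n",
                x$kind))
  invisible(x)
}

#' Per-capita long-term reproductive value
#'
#' Proportional to \eqn{\pi(x)/\phi(x)}, where \eqn{\pi} is the stationary
#' distribution of the lineage diffusion and \eqn{\phi} the population
#' profile.  For a stationary lab-frame source with gradient drift
#' (\eqn{b = \nabla h}), \eqn{\pi(x) \propto (\gamma/r)\phi^2 e^{-2h/\sigma^2}}
#' so the reproductive value is \eqn{\propto (\gamma/r)\phi}.
#'
#' @param source a \code{\link{wave_frame_model}} or
#'   \code{\link{stationary_source}}.
#' @param grid evaluation grid.
#' @return list with \code{x}, \code{value} (normalised to integrate to 1),
#'   and \code{integrable}; when the stationary density does not exist the
#'   result is flagged and carries no values.
#' @export
reproductive_value <- function(source, grid) {
  sd <- stationary_density(source, grid)
  if (!isTRUE(sd$integrable))
    return(list(x = grid, value = NULL, integrable = FALSE,
                reason = sd$reason))
  phi <- if (inherits(source, "wave_frame_model"))
    wave_profile(source, grid) else source$phi_fn(grid)
  v <- sd$density / pmax(phi, 1e-300)
  dxg <- diff(grid)
  Z <- sum((v[-1] + v[-length(v)]) / 2 * dxg)
  list(x = grid, value = v / Z, integrable = TRUE)
}
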