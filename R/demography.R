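#' Demography: rates, kernels and scaling parameters
#'
#' Bundles the three demographic ingredients — the birth rate \code{gamma},
#' the establishment probability \code{r}, and the net-reproduction function
#' \code{F} — together with the smoothing kernels through which each measures
#' local density, and the scaling parameters \code{theta} (time scale) and
#' \code{N} (density scale).  The per-capita death rate is derived as
#' \deqn{\mu_\theta(x) = r(x, m_r)\,\gamma(x, m_\gamma) - F(x, m_F)/\theta,}
#' where each density argument is smoothed by the corresponding kernel.  The
#' construction validates that \eqn{\mu_\theta \ge 0} and \eqn{0 \le r \le 1}
#' on a density grid \eqn{[0, m_{max}]}.
#'
#' @param gamma,r,F \code{\link{rate_fn}} objects (or names understood by
#'   \code{rate_fn} with default parameters).
#' @param theta positive time-scaling parameter.
#' @param N positive density scale.
#' @param kernels named list with elements \code{gamma}, \code{r}, \code{F},
#'   each a \code{\link{kernel_spec}}.  A single \code{kernel_spec} is
#'   recycled to all three.
#' @param m_max upper end of the admissible-density validation grid.
#' @param m_min lower end of the admissible density range.  Parameterisations
#'   whose birth rate grows linearly in density (the porous-medium preset
#'   \eqn{\gamma = m}, \eqn{F = 1-m}, for which \eqn{\mu_\theta =
#'   (1+1/\theta)m - 1/\theta}) have nonnegative death rates only for
#'   \eqn{m \ge 1/(\theta+1)} and must declare that bound here; the death
#'   rate still errors (never clips) if a density below the declared range is
#'   encountered at run time.
#' @return an object of class \code{demography} with derived field
#'   \code{alpha = theta/N}.
#' @export
demography <- function(gamma, r, F, theta, N, kernels, m_max = 10, m_min = 0) {
  as_rate <- function(f) if (inherits(f, "rate_fn")) f else rate_fn(f)
  gamma <- as_rate(gamma); r <- as_rate(r); F <- as_rate(F)
  stopifnot(theta > 0, N > 0, m_max > m_min, m_min >= 0)
  if (inherits(kernels, "kernel_spec"))
    kernels <- list(gamma = kernels, r = kernels, F = kernels)
  stopifnot(all(c("gamma", "r", "F") %in% names(kernels)))
  dem <- structure(
    list(gamma_fn = gamma, r_fn = r, F_fn = F,
         theta = theta, N = N, alpha = theta / N,
         kernels = kernels, m_max = m_max, m_min = m_min),
    class = "demography")
  validate_demography(dem)
  dem
}

validate_demography <- function(dem, n_grid = 201L) {
  m <- seq(dem$m_min, dem$m_max, length.out = n_grid)
  rv <- dem$r_fn(0, m)
  if (any(rv < -1e-12 | rv > 1 + 1e-12))
    stop("establishment probability r must lie in [0, 1] on [0, m_max]")
  gv <- dem$gamma_fn(0, m)
  if (any(gv < 0)) stop("birth rate gamma must be nonnegative")
  if (is.finite(rate_cap(dem$gamma_fn)) &&
      any(gv > rate_cap(dem$gamma_fn) + 1e-12))
    stop("gamma exceeds its declared cap")
  mu <- rv * gv - dem$F_fn(0, m) / dem$theta
  if (any(mu < -1e-12)) {
    bad <- m[which.min(mu)]
    stop(sprintf(
      "nonpositive death rate: mu_theta = %g at m = %g (x = 0); ",
      min(mu), bad),
      "the model requires r*gamma >= F/theta on the admissible density range")
  }
  ## sufficient condition for well-behaved nonlocal limits when both kernels
  ## are Gaussian: sigma_gamma > sigma_r (checked, not enforced)
  kg <- dem$kernels$gamma; kr <- dem$kernels$r
  if (kg$family == "gaussian" && kr$family == "gaussian" &&
      kg$scale <= kr$scale && kg$scale != kr$scale)
    warning("Gaussian kernels with scale(gamma) < scale(r); ",
            "the sufficient regularity condition scale(gamma) > scale(r) fails",
            call. = FALSE)
  invisible(dem)
}

#' @export
print.demography <- function(x, ...) {
  cat(sprintf("<demography: gamma=%s, r=%s, F=%s; theta=%g, N=%g, alpha=%g>\n",
              rate_name(x$gamma_fn), rate_name(x$r_fn), rate_name(x$F_fn),
              x$theta, x$N, x$alpha))
  invisible(x)
}

#' Per-capita death rate
#'
#' \eqn{\mu_\theta = r(x, m_r)\gamma(x, m_\gamma) - F(x, m_F)/\theta}, where
#' the three arguments are the local densities smoothed by the \code{r},
#' \code{gamma} and \code{F} kernels respectively.  A negative value is an
#' error (the model assumes nonnegative death rates); it is never clipped.
#'
#' @param dem a \code{\link{demography}}.
#' @param x location(s).
#' @param m_r,m_gamma,m_F kernel-smoothed densities at \code{x} (vectorised).
#' @return nonnegative death rate(s).
#' @export
death_rate <- function(dem, x, m_r, m_gamma, m_F) {
  mu <- dem$r_fn(x, m_r) * dem$gamma_fn(x, m_gamma) - dem$F_fn(x, m_F) / dem$theta
  if (any(mu < 0)) {
    i <- which.min(mu)
    stop(sprintf(
      "nonpositive death rate mu_theta = %g at x = %s (m_r = %g, m_gamma = %g, m_F = %g)",
      mu[i], toString(signif(if (is.matrix(x)) x[i, ] else x[min(i, length(x))], 4)),
      m_r[min(i, length(m_r))], m_gamma[min(i, length(m_gamma))],
      m_F[min(i, length(m_F))]))
  }
  mu
}

#' Dispersal specification
#'
#' Offspring displacement is Gaussian with mean \code{b(x)/theta} and
#' covariance \code{C(x)/theta}: the mean and covariance of the unscaled
#' kernel are divided by \code{theta}.
#'
#' @param theta time-scaling parameter (shared with the demography).
#' @param sigma2 scalar shorthand for isotropic covariance \code{C = sigma2 I}.
#' @param mean_fn mean displacement per unit unscaled time: a constant vector
#'   or a function of location returning one.
#' @param cov_fn covariance: a constant SPD matrix (or scalar in 1-d) or a
#'   function of location returning one.  Overrides \code{sigma2}.
#' @param dim spatial dimension.
#' @return an object of class \code{dispersal_spec}.
#' @export
dispersal_spec <- function(theta, sigma2 = 1, mean_fn = NULL, cov_fn = NULL,
                           dim = 1L) {
  dim <- as.integer(dim)
  stopifnot(theta > 0, dim %in% c(1L, 2L))
  if (is.null(mean_fn)) mean_fn <- rep(0, dim)
  if (is.null(cov_fn)) cov_fn <- diag(sigma2, dim)
  b_fn <- if (is.function(mean_fn)) mean_fn else {
    b0 <- rep_len(as.numeric(mean_fn), dim); function(x) b0
  }
  C_fn <- if (is.function(cov_fn)) cov_fn else {
    C0 <- if (is.matrix(cov_fn)) cov_fn else diag(as.numeric(cov_fn), dim)
    function(x) C0
  }
  probe <- C_fn(if (dim == 1L) 0 else c(0, 0))
  ev <- eigen(probe, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("dispersal covariance must be strictly positive definite")
  iso <- !is.function(cov_fn) && !is.matrix(cov_fn)
  structure(list(theta = theta, b_fn = b_fn, C_fn = C_fn, dim = dim,
                 sigma2 = if (iso) as.numeric(cov_fn) else NA_real_),
            class = "dispersal_spec")
}

#' Sample a dispersal displacement
#'
#' Draws the offspring location \eqn{y = x + b(x)/\theta + K(x) z/\sqrt\theta}
#' with \eqn{z} standard normal and \eqn{K K^T = C} the Cholesky factor.
#' Positions are wrapped into the domain when it is periodic.  Uses the R
#' random number stream.
#'
#' @param disp a \code{\link{dispersal_spec}}.
#' @param x parent location(s): vector (1-d, vectorised) or a single 2-vector.
#' @param domain optional \code{\link{domain_spec}} for wrapping.
#' @return offspring location(s).
#' @export
sample_dispersal <- function(disp, x, domain = NULL) {
  th <- disp$theta
  if (disp$dim == 1L) {
    x <- as.numeric(x)
    n <- length(x)
    b <- vapply(x, function(xi) disp$b_fn(xi)[1], 0)
    s <- vapply(x, function(xi) sqrt(disp$C_fn(xi)[1, 1]), 0)
    y <- x + b / th + s * stats::rnorm(n) / sqrt(th)
  } else {
    b <- disp$b_fn(x)
    K <- chol(disp$C_fn(x))
    y <- x + b / th + drop(crossprod(K, stats::rnorm(2))) / sqrt(th)
  }
  if (!is.null(domain)) y <- wrap_positions(y, domain)
  y
}

## theta * integral of f(y) q_theta(x, dy) helpers use Gauss-Hermite nodes.
## Returns nodes and weights for E[f(Y)], Y ~ N(mu, sd^2): sum w_i f(mu + sd t_i)
gh_rule <- function(M = 20L) {
  gh <- pracma::gaussHermite(M)
  list(t = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}
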