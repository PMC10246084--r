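#' Dispersion-relation specification
#'
#' Ingredients of the linear stability analysis of the spatially constant
#' equilibrium \eqn{\phi \equiv \phi_0} of the nonlocal equation in one
#' dimension: linearising around \eqn{\phi_0} and taking Fourier transforms
#' gives a per-mode growth rate
#' \deqn{\lambda(u) = -u^2\sigma^2\phi_0 r_0\gamma_0'\,\hat\rho_\gamma(u)
#'   - u^2\sigma^2 r_0\gamma_0 + \phi_0 F_0'\,\hat\rho_F(u),}
#' where \eqn{\sigma^2} is the coefficient of \eqn{\Delta} in the smooth
#' density equation (half the dispersal variance \eqn{C}) and the kernel
#' transforms are normalised so that \eqn{\hat\rho(0) = 1} (i.e.
#' \eqn{\int e^{iux}\rho(x)dx}; \eqn{2\pi} times
#' \code{\link{kernel_fourier}}), which is the normalisation under which
#' \eqn{\lambda(u)} is the exact exponential rate of a small single-mode
#' perturbation of the nonlocal PDE.
#'
#' @param phi0 equilibrium density (\eqn{F(\phi_0) = 0}).
#' @param r0,gamma0 rates at the equilibrium.
#' @param gamma0p \eqn{\partial_m\gamma} at the equilibrium.
#' @param F0p \eqn{\partial_m F} at the equilibrium; must be negative (the
#'   nonspatial equilibrium must be stable).
#' @param sigma2 diffusion coefficient (half the dispersal variance).
#' @param kernel_gamma,kernel_F \code{\link{kernel_spec}}s (1-d).
#' @return an object of class \code{dispersion_spec}.
#' @export
dispersion_spec <- function(phi0, r0 = 1, gamma0 = 1, gamma0p = 0, F0p,
                            sigma2, kernel_gamma = NULL, kernel_F) {
  stopifnot(phi0 > 0, F0p < 0, sigma2 > 0)
  if (is.null(kernel_gamma)) kernel_gamma <- kernel_F
  stopifnot(kernel_F$dim == 1L, kernel_gamma$dim == 1L)
  structure(list(phi0 = phi0, r0 = r0, gamma0 = gamma0, gamma0p = gamma0p,
                 F0p = F0p, sigma2 = sigma2,
                 kernel_gamma = kernel_gamma, kernel_F = kernel_F),
            class = "dispersion_spec")
}

#' Build a dispersion spec from a demography
#'
#' Evaluates the rates and their density-derivatives at the equilibrium of
#' \code{dem} and extracts \eqn{\sigma^2 = C/2} from the dispersal.
#'
#' @param dem a \code{\link{demography}}.
#' @param disp a \code{\link{dispersal_spec}}.
#' @param phi0 equilibrium (computed with \code{\link{equilibrium_density}}
#'   by default).
#' @return a \code{\link{dispersion_spec}}.
#' @export
dispersion_spec_from <- function(dem, disp, phi0 = NULL) {
  if (is.null(phi0))
    phi0 <- equilibrium_density(dem)
  dispersion_spec(
    phi0 = phi0,
    r0 = dem$r_fn(0, phi0),
    gamma0 = dem$gamma_fn(0, phi0),
    gamma0p = rate_deriv_m(dem$gamma_fn, phi0),
    F0p = rate_deriv_m(dem$F_fn, phi0),
    sigma2 = disp$C_fn(0)[1, 1] / 2,
    kernel_gamma = dem$kernels$gamma,
    kernel_F = dem$kernels$F)
}

#' Nontrivial spatially constant equilibrium
#'
#' Finds \eqn{\phi_0 > 0} with \eqn{F(\phi_0) = 0} by bisection (to 1e-10)
#' after a sign-change scan on \eqn{(0, m_{max}]}, and verifies
#' \eqn{F'(\phi_0) < 0} by finite differences.  For models specified through
#' \eqn{(\gamma, \mu)} rather than \eqn{F}, pass \eqn{F(m) =
#' r(m)\gamma(m) - \mu(m)} as a function.
#'
#' @param dem a \code{\link{demography}}, a \code{\link{rate_fn}}, or a plain
#'   function \code{F(m)}.
#' @param m_max upper search bound (taken from the demography if available).
#' @param stable if TRUE (default) return only roots with \eqn{F' < 0};
#'   otherwise all roots.
#' @return equilibrium density (or vector of roots when \code{stable=FALSE}
#'   finds several).
#' @export
equilibrium_density <- function(dem, m_max = NULL, stable = TRUE) {
  if (inherits(dem, "demography")) {
    Ff <- function(m) dem$F_fn(0, m)
    if (is.null(m_max)) m_max <- dem$m_max
  } else if (is.function(dem)) {
    Ff <- if (inherits(dem, "rate_fn")) function(m) dem(0, m) else dem
    if (is.null(m_max)) m_max <- 10
  } else stop("pass a demography or a function F(m)")
  grid <- seq(m_max / 2000, m_max, length.out = 2000)
  v <- vapply(grid, Ff, 0)
  sgn <- which(v[-1] * v[-length(v)] <= 0 & v[-length(v)] != 0)
  if (length(sgn) == 0L)
    stop("no equilibrium: F has no sign change on (0, m_max]")
  roots <- vapply(sgn, function(i)
    stats::uniroot(Ff, c(grid[i], grid[i + 1]), tol = 1e-12)$root, 0)
  roots <- unique(round(roots, 10))
  h <- 1e-6
  Fp <- vapply(roots, function(m) (Ff(m + h) - Ff(m - h)) / (2 * h), 0)
  if (stable) {
    keep <- roots[Fp < 0]
    if (length(keep) == 0L)
      stop("no stable equilibrium: F' >= 0 at every root")
    keep[1]
  } else roots
}

#' Linear growth rate of a spatial Fourier mode
#'
#' Evaluates the dispersion relation \eqn{\lambda(u)} of a perturbation
#' \eqn{e^{iux}} around the constant equilibrium (see
#' \code{\link{dispersion_spec}} for the formula and the transform
#' normalisation).  Negative for all \eqn{u > 0} when both kernels are
#' Gaussian and \eqn{\gamma_0' = 0}; positive on a band inside
#' \eqn{(\pi/\epsilon, 2\pi/\epsilon)} for a top-hat competition kernel with
#' \eqn{\sigma^2/\epsilon^2} small — the clumping instability.
#'
#' @param u wavenumber(s).
#' @param spec a \code{\link{dispersion_spec}}.
#' @return growth rate(s) \eqn{\lambda(u)}.
#' @export
growth_rate <- function(u, spec) {
  stopifnot(inherits(spec, "dispersion_spec"))
  rg_hat <- 2 * pi * kernel_fourier(spec$kernel_gamma, u)
  rF_hat <- 2 * pi * kernel_fourier(spec$kernel_F, u)
  -u^2 * spec$sigma2 * spec$phi0 * spec$r0 * spec$gamma0p * rg_hat -
    u^2 * spec$sigma2 * spec$r0 * spec$gamma0 +
    spec$phi0 * spec$F0p * rF_hat
}

#' Unstable wavenumber band
#'
#' Evaluates \code{\link{growth_rate}} on a grid, brackets sign changes,
#' refines the band edges by bisection, and locates the dominant (fastest
#' growing) wavenumber.
#'
#' @param spec a \code{\link{dispersion_spec}}.
#' @param u_grid increasing positive wavenumber grid.
#' @return an object of class \code{dispersion_result}: the grid, the rates,
#'   a matrix of unstable \code{intervals} (possibly 0 rows), and the
#'   dominant wavenumber \code{u_star} (NA when stable).
#' @export
unstable_band <- function(spec, u_grid = seq(0.01, 20, length.out = 2000)) {
  stopifnot(all(diff(u_grid) > 0), all(u_grid > 0))
  lam <- growth_rate(u_grid, spec)
  f <- function(u) growth_rate(u, spec)
  pos <- lam > 0
  intervals <- NULL
  if (any(pos)) {
    runs <- rle(pos)
    ends <- cumsum(runs$lengths)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    for (j in which(runs$values)) {
      i0 <- starts[j]; i1 <- ends[j]
      lo <- if (i0 > 1L)
        stats::uniroot(f, c(u_grid[i0 - 1L], u_grid[i0]), tol = 1e-10)$root
      else u_grid[1L]
      hi <- if (i1 < length(u_grid))
        stats::uniroot(f, c(u_grid[i1], u_grid[i1 + 1L]), tol = 1e-10)$root
      else u_grid[length(u_grid)]
      intervals <- rbind(intervals, c(lo, hi))
    }
  }
  u_star <- if (any(pos)) {
    i <- which.max(lam)
    stats::optimize(f, c(u_grid[max(1, i - 1)], u_grid[min(length(u_grid), i + 1)]),
                    maximum = TRUE)$maximum
  } else NA_real_
  structure(list(u = u_grid, lambda = lam,
                 intervals = if (is.null(intervals))
                   matrix(0, 0, 2) else intervals,
                 u_star = u_star),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  if (nrow(x$intervals) == 0L)
    cat("<dispersion_result: stable (lambda <= 0 on the grid)>\n")
  else
    cat(sprintf("<dispersion_result: %d unstable band(s), u* = %g (wavelength %g)>\n",
                nrow(x$intervals), x$u_star, 2 * pi / x$u_star))
  invisible(x)
}

#' Predicted versus realised clump wavelength
#'
#' Closes the loop between the linear dispersion relation and the nonlinear
#' pattern: runs \code{\link{solve_nonlocal}} from the constant equilibrium
#' plus small white noise until the pattern amplitude saturates, extracts the
#' dominant wavelength from the spatial power spectrum, and compares it to
#' the linear prediction \eqn{2\pi/u^*}.
#'
#' @param spec a \code{\link{dispersion_spec}} (for the prediction).
#' @param dem,disp the matching nonlocal model.
#' @param L domain length; \code{dx}, \code{dt}, \code{T} solver controls.
#' @param noise_amp initial white-noise amplitude.
#' @return list with \code{predicted} (\eqn{2\pi/u^*}, NA if stable),
#'   \code{observed} (spectral-peak wavelength, NA if the pattern decayed),
#'   and the final pattern \code{amplitude}.
#' @export
predicted_vs_observed_wavelength <- function(spec, dem, disp, L = 28,
                                             dx = 0.05, dt = 0.02, T = 60,
                                             noise_amp = 1e-3) {
  band <- unstable_band(spec)
  predicted <- if (nrow(band$intervals) > 0) 2 * pi / band$u_star else NA_real_
  xg <- seq(0, L - dx, by = dx)
  phi0 <- density_field(xg, spec$phi0 + noise_amp * stats::rnorm(length(xg)),
                        boundary = "periodic")
  traj <- solve_nonlocal(phi0, dem, disp, T = T, dt = dt,
                         record_every = T / 4)
  vfin <- traj$values[[length(traj$values)]]
  amp <- (max(vfin) - min(vfin)) / 2
  observed <- NA_real_
  if (amp > 10 * noise_amp) {
    sp <- Mod(stats::fft(vfin - mean(vfin)))^2
    n <- length(vfin)
    kmax <- which.max(sp[2:floor(n / 2)])  # skip the zero mode
    observed <- L / kmax
  }
  list(predicted = predicted, observed = observed, amplitude = amp,
       band = band)
}
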