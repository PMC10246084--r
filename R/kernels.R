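#' Smoothing kernel specification
#'
#' A smoothing kernel used to measure local population density by convolution
#' with the scaled atomic population measure.  Two closed-form families are
#' supported: an isotropic Gaussian density with standard deviation
#' \code{scale}, and (in one dimension) a top-hat (uniform) kernel of
#' half-width \code{scale}.
#'
#' @param family one of \code{"gaussian"}, \code{"tophat"}.
#' @param scale positive real; standard deviation for the Gaussian family,
#'   half-width for the top-hat family.
#' @param dim spatial dimension, 1 or 2.  The top-hat family is 1-d only.
#' @return an object of class \code{kernel_spec}.
#' @export
kernel_spec <- function(family = c("gaussian", "tophat"), scale, dim = 1L) {
  family <- match.arg(family)
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  dim <- as.integer(dim)
  if (!dim %in% c(1L, 2L)) stop("kernel dimension must be 1 or 2")
  if (family == "tophat" && dim != 1L)
    stop("top-hat kernel is only implemented in dimension 1")
  structure(list(family = family, scale = scale, dim = dim),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec: %s, scale = %g, dim = %d>\n",
              x$family, x$scale, x$dim))
  invisible(x)
}

#' Pointwise kernel evaluation
#'
#' Evaluates the kernel density rho at displacements \code{x}.  For vector
#' input in 1-d, evaluation is vectorised over displacements; in 2-d,
#' \code{x} may be a matrix with one displacement per row.
#'
#' @param k a \code{\link{kernel_spec}}.
#' @param x displacement(s): numeric vector (1-d) or 2-column matrix (2-d).
#' @return nonnegative kernel values.
#' @export
kernel_value <- function(k, x) {
  stopifnot(inherits(k, "kernel_spec"))
  if (k$dim == 1L) {
    x <- as.numeric(x)
    if (k$family == "gaussian") {
      stats::dnorm(x, sd = k$scale)
    } else {
      ifelse(abs(x) <= k$scale, 1 / (2 * k$scale), 0)
    }
  } else {
    if (is.null(dim(x))) x <- matrix(x, ncol = 2L)
    r2 <- rowSums(x^2)
    exp(-r2 / (2 * k$scale^2)) / (2 * pi * k$scale^2)
  }
}

#' Kernel Fourier transform (1-d)
#'
#' Returns the transform \eqn{\hat\rho(u) = \int e^{iux}\rho(x)\,dx / (2\pi)}.
#' Under this convention \eqn{\hat\rho(0) = 1/(2\pi)} for any normalised
#' kernel.  Closed forms: Gaussian \eqn{e^{-s^2u^2/2}/(2\pi)}; top-hat of
#' half-width \eqn{\epsilon}: \eqn{\sin(\epsilon u)/(2\pi\epsilon u)}, with
#' the limit \eqn{1/(2\pi)} at \eqn{u=0}.  The top-hat transform is negative
#' on \eqn{(\pi/\epsilon, 2\pi/\epsilon)}, which is what makes clumping
#' instabilities possible.
#'
#' @param k a \code{\link{kernel_spec}} with \code{dim = 1}.
#' @param u numeric vector of wavenumbers.
#' @return numeric vector of transform values.
#' @export
kernel_fourier <- function(k, u) {
  stopifnot(inherits(k, "kernel_spec"))
  if (k$dim != 1L)
    stop("kernel_fourier is only defined for 1-dimensional kernels")
  u <- as.numeric(u)
  if (k$family == "gaussian") {
    exp(-k$scale^2 * u^2 / 2) / (2 * pi)
  } else {
    eps <- k$scale
    out <- ifelse(u == 0, 1 / (2 * pi), sin(eps * u) / (2 * pi * eps * u))
    out
  }
}

## Kernel sampled on a periodic grid, normalised so that discrete convolution
## preserves total mass exactly (sum(kd) * dx == 1).
kernel_grid <- function(k, x_grid, length_domain) {
  dx <- x_grid[2] - x_grid[1]
  ## wrap displacements from grid origin into [-L/2, L/2)
  disp <- x_grid - x_grid[1]
  disp <- ((disp + length_domain / 2) %% length_domain) - length_domain / 2
  kd <- kernel_value(k, disp)
  s <- sum(kd) * dx
  if (s <= 0) stop("kernel has no support on the grid")
  kd / s * (1 / dx) * dx   # normalised: sum(kd)*dx == 1
}
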