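#' Spatial domain
#'
#' @param dim spatial dimension (1 or 2).
#' @param lengths numeric vector of side lengths (recycled to \code{dim}).
#' @param boundary \code{"periodic"} (default; distances use the minimal
#'   image) or \code{"none"} (free space, used mainly for dispersal tests).
#' @return an object of class \code{domain_spec}.
#' @export
domain_spec <- function(dim = 1L, lengths = 50, boundary = c("periodic", "none")) {
  boundary <- match.arg(boundary)
  dim <- as.integer(dim)
  stopifnot(dim %in% c(1L, 2L), all(lengths > 0))
  lengths <- rep_len(as.numeric(lengths), dim)
  structure(list(dim = dim, lengths = lengths, boundary = boundary),
            class = "domain_spec")
}

## wrap positions into [0, L) on periodic domains
wrap_positions <- function(x, domain) {
  if (domain$boundary != "periodic") return(x)
  if (domain$dim == 1L) {
    x %% domain$lengths[1]
  } else {
    sweep(x, 2L, domain$lengths, "%%")
  }
}

## displacement a - b through the minimal image
min_image <- function(d, length_domain) {
  ((d + length_domain / 2) %% length_domain) - length_domain / 2
}

#' Point population
#'
#' The state of the individual-based model: a set of atoms of mass
#' \code{1/N}.  The scaled population measure assigns mass 1/N to each
#' position, so the total mass is \code{n/N}.
#'
#' @param positions numeric vector (1-d) or n x 2 matrix (2-d) of locations.
#' @param N density scale; each individual carries mass \code{1/N}.
#' @param domain a \code{\link{domain_spec}}.
#' @param time current scaled time.
#' @return an object of class \code{point_population}.
#' @export
point_population <- function(positions, N, domain, time = 0) {
  stopifnot(inherits(domain, "domain_spec"), N > 0)
  if (domain$dim == 1L) {
    positions <- as.numeric(positions)
  } else {
    if (is.null(dim(positions))) positions <- matrix(positions, ncol = 2L)
    stopifnot(ncol(positions) == 2L)
  }
  positions <- wrap_positions(positions, domain)
  structure(list(positions = positions, N = N, domain = domain, time = time),
            class = "point_population")
}

#' @export
print.point_population <- function(x, ...) {
  cat(sprintf("<point_population: n = %d, N = %g, mass = %g, t = %g>\n",
              pop_size(x), x$N, pop_size(x) / x$N, x$time))
  invisible(x)
}

#' Number of individuals in a population
#' @param pop a \code{\link{point_population}}.
#' @return integer count.
#' @export
pop_size <- function(pop) {
  if (pop$domain$dim == 1L) length(pop$positions) else nrow(pop$positions)
}

#' Total scaled mass of a population
#' @param pop a \code{\link{point_population}}.
#' @return \code{n/N}.
#' @export
total_mass <- function(pop) pop_size(pop) / pop$N

#' Kernel-smoothed local density at query points
#'
#' Local density is the convolution of the scaled atomic measure with the
#' kernel: \eqn{(1/N)\sum_i \rho(x - x_i)}, with displacements computed
#' through the minimal image on periodic domains.  An individual's own atom
#' contributes \eqn{\rho(0)/N} to the density at its location.
#'
#' @param pop a \code{\link{point_population}}.
#' @param k a \code{\link{kernel_spec}} of matching dimension.
#' @param x query location(s); vector (1-d) or matrix with one row per query
#'   (2-d).
#' @return numeric vector of densities, one per query point.
#' @export
local_density <- function(pop, k, x) {
  stopifnot(inherits(pop, "point_population"), inherits(k, "kernel_spec"))
  if (k$dim != pop$domain$dim) stop("kernel and population dimension differ")
  n <- pop_size(pop)
  if (pop$domain$dim == 1L) {
    x <- as.numeric(x)
    if (n == 0L) return(numeric(length(x)))
    d <- outer(x, pop$positions, "-")
    if (pop$domain$boundary == "periodic")
      d <- min_image(d, pop$domain$lengths[1])
    rowSums(matrix(kernel_value(k, d), nrow = length(x))) / pop$N
  } else {
    if (is.null(dim(x))) x <- matrix(x, ncol = 2L)
    if (n == 0L) return(numeric(nrow(x)))
    out <- numeric(nrow(x))
    for (j in seq_len(nrow(x))) {
      d1 <- x[j, 1] - pop$positions[, 1]
      d2 <- x[j, 2] - pop$positions[, 2]
      if (pop$domain$boundary == "periodic") {
        d1 <- min_image(d1, pop$domain$lengths[1])
        d2 <- min_image(d2, pop$domain$lengths[2])
      }
      out[j] <- sum(kernel_value(k, cbind(d1, d2)))
    }
    out / pop$N
  }
}
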