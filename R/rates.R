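#' Demographic rate function registry
#'
#' Demographic rates (birth rate gamma, establishment probability r, and the
#' net-reproduction function F) are functions of location \code{x} and local
#' density \code{m}.  To keep model configurations serialisable, rates are
#' chosen from a closed registry of named parametric forms:
#'
#' \describe{
#'   \item{\code{constant(c)}}{\eqn{c}, independent of \code{x} and \code{m}.}
#'   \item{\code{logistic_F}}{\eqn{F(m) = 1 - m}.}
#'   \item{\code{bistable_F(s)}}{\eqn{F(m) = (1-m)(2m-1+s)}.}
#'   \item{\code{linear_gamma(cap)}}{\eqn{\gamma(m) = \min(m, cap)}; the cap
#'     (default 20) keeps the birth rate bounded, the unbounded case being
#'     recovered in practice because logistic control keeps densities small.}
#'   \item{\code{saturating_gamma(a, b)}}{\eqn{\gamma(m) = a/(b+m)}.}
#'   \item{\code{tabulated(m, values)}}{linear interpolation in \code{m},
#'     constant extrapolation.}
#'   \item{\code{spatial(fn, cap)}}{an arbitrary function
#'     \code{fn(x, m)} of location and density (for spatially inhomogeneous
#'     examples; not serialisable, flagged as such).}
#' }
#'
#' @param name registry name, see Details.
#' @param ... parameters of the chosen form.
#' @return an object of class \code{rate_fn}: callable as \code{f(x, m)}
#'   (vectorised over both), with attributes \code{name}, \code{params},
#'   \code{cap} (an upper bound, possibly \code{Inf}).
#' @export
rate_fn <- function(name, ...) {
  params <- list(...)
  p <- function(key, default) {
    if (!is.null(params[[key]])) params[[key]] else default
  }
  f <- switch(name,
    constant = {
      c0 <- p("c", 1)
      function(x, m) rep_len(c0, max(length(m), NROW(x)))
    },
    logistic_F = function(x, m) 1 - m,
    bistable_F = {
      s <- p("s", 0.5)
      function(x, m) (1 - m) * (2 * m - 1 + s)
    },
    linear_gamma = {
      cap <- p("cap", 20)
      function(x, m) pmin(m, cap)
    },
    saturating_gamma = {
      a <- p("a", 3); b <- p("b", 1)
      function(x, m) a / (b + m)
    },
    tabulated = {
      mm <- params$m; vv <- params$values
      stopifnot(length(mm) == length(vv), length(mm) >= 2)
      function(x, m) stats::approx(mm, vv, xout = m, rule = 2)$y
    },
    spatial = {
      fn <- params$fn
      stopifnot(is.function(fn))
      fn
    },
    stop("unknown rate function: ", name)
  )
  cap <- switch(name,
    constant = p("c", 1),
    logistic_F = Inf,
    bistable_F = Inf,
    linear_gamma = p("cap", 20),
    saturating_gamma = p("a", 3) / p("b", 1),
    tabulated = max(params$values),
    spatial = p("cap", Inf)
  )
  structure(f, class = "rate_fn", name = name, params = params, cap = cap)
}

#' @export
print.rate_fn <- function(x, ...) {
  cat(sprintf("<rate_fn: %s>\n", attr(x, "name")))
  invisible(x)
}

rate_name <- function(f) attr(f, "name")
rate_cap <- function(f) attr(f, "cap")

## TRUE if the rate does not depend on x or m (fast paths in the lookdown).
rate_is_constant <- function(f) identical(rate_name(f), "constant")

## dF/dm at m by central difference (used for equilibrium checks and the
## dispersion relation on tabulated forms).
rate_deriv_m <- function(f, m, x = 0, h = 1e-6) {
  (f(x, m + h) - f(x, m - h)) / (2 * h)
}
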