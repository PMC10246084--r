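#' Initial-condition fixtures
#'
#' Generates the standard initial conditions used across the package:
#' \describe{
#'   \item{\code{poisson_uniform}}{homogeneous Poisson point cloud: a
#'     \code{\link{point_population}} with \code{Poisson(N * density * volume)}
#'     individuals placed uniformly in a sub-box of the domain.}
#'   \item{\code{block}}{density 1 on a box, 0 elsewhere: a Poisson population
#'     restricted to the box, or (when \code{dx} is supplied) the
#'     corresponding Heaviside \code{\link{density_field}}.}
#'   \item{\code{wave_profile}}{a \code{\link{density_field}} sampled from the
#'     closed-form travelling-wave profile of a
#'     \code{\link{wave_frame_model}}.}
#' }
#' Uses the R random number stream; call \code{set.seed} for reproducibility.
#'
#' @param kind one of \code{"poisson_uniform"}, \code{"block"},
#'   \code{"wave_profile"}.
#' @param params a named list; see Details.  Common fields: \code{domain}
#'   (a \code{\link{domain_spec}}), \code{N}, \code{density}, \code{box}
#'   (length-2 interval, default the whole domain), \code{dx}, \code{model}
#'   (a \code{wave_frame_model}), \code{boundary}, \code{front_at}.
#' @return a \code{point_population} or \code{density_field}.
#' @export
make_fixture <- function(kind = c("poisson_uniform", "block", "wave_profile"),
                         params = list()) {
  kind <- match.arg(kind)
  p <- params
  if (kind == "poisson_uniform") {
    stopifnot(!is.null(p$domain), !is.null(p$N))
    density <- if (is.null(p$density)) 1 else p$density
    box <- if (is.null(p$box)) c(0, p$domain$lengths[1]) else p$box
    if (p$domain$dim == 1L) {
      vol <- diff(box)
      n <- stats::rpois(1, p$N * density * vol)
      point_population(stats::runif(n, box[1], box[2]), p$N, p$domain)
    } else {
      vol <- prod(p$domain$lengths)
      n <- stats::rpois(1, p$N * density * vol)
      point_population(cbind(stats::runif(n, 0, p$domain$lengths[1]),
                             stats::runif(n, 0, p$domain$lengths[2])),
                       p$N, p$domain)
    }
  } else if (kind == "block") {
    if (!is.null(p$dx)) {
      L <- p$L
      xg <- seq(0, L - p$dx, by = p$dx)
      edge <- if (is.null(p$edge)) L / 10 else p$edge
      density_field(xg, as.numeric(xg < edge),
                    boundary = if (is.null(p$boundary)) "neumann" else p$boundary)
    } else {
      stopifnot(!is.null(p$domain), !is.null(p$N))
      box <- if (is.null(p$box)) c(0, p$domain$lengths[1]) else p$box
      if (diff(box) <= 0)
        return(point_population(numeric(0), p$N, p$domain))
      n <- stats::rpois(1, p$N * diff(box))
      point_population(stats::runif(n, box[1], box[2]), p$N, p$domain)
    }
  } else {
    stopifnot(!is.null(p$model), !is.null(p$L), !is.null(p$dx))
    xg <- seq(0, p$L - p$dx, by = p$dx)
    front <- if (is.null(p$front_at)) p$L / 2 else p$front_at
    model <- p$model
    if (model$kind == "pme_logistic") model$x0 <- 0
    vals <- wave_profile(model, xg - front)
    density_field(xg, vals,
                  boundary = if (is.null(p$boundary)) "neumann" else p$boundary)
  }
}
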