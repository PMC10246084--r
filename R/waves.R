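#' Travelling-wave frame models
#'
#' The three reference waves used throughout the package, each a travelling
#' front \eqn{\phi(t,x) = w(x - ct)} of a 1-d equation with \eqn{\sigma^2=2},
#' \eqn{b=0}:
#' \describe{
#'   \item{\code{fisher_kpp}}{\eqn{\partial_t\phi = \partial_{xx}\phi +
#'     \phi(1-\phi)}; \eqn{r=\gamma=1}; minimal speed \eqn{c=2}; no closed-form
#'     profile (obtained by relaxation in the co-moving frame).}
#'   \item{\code{allen_cahn}}{\eqn{\partial_t\phi = \partial_{xx}\phi +
#'     \phi(1-\phi)(2\phi-1+s)}; \eqn{r=\gamma=1}; speed \eqn{c=s};
#'     profile \eqn{w_A(x) = (1+e^x)^{-1}}.}
#'   \item{\code{pme_logistic}}{\eqn{\partial_t\phi = \partial_{xx}(\phi^2) +
#'     \phi(1-\phi)}; \eqn{r=1}, \eqn{\gamma(x,m)=m}; speed \eqn{c=1};
#'     profile \eqn{w_P(x) = (1 - e^{(x-x_0)/2})_+} with a sharp front at
#'     \eqn{x_0}.}
#' }
#'
#' @param kind one of \code{"fisher_kpp"}, \code{"allen_cahn"},
#'   \code{"pme_logistic"}.
#' @param s Allen-Cahn asymmetry parameter in (0, 2); the wave speed.
#' @param x0 front location for the porous-medium profile (default 0).
#' @return an object of class \code{wave_frame_model} with fields
#'   \code{kind}, \code{speed}, \code{sigma2 = 2}, \code{b = 0}, \code{s},
#'   \code{x0}.
#' @export
wave_frame_model <- function(kind = c("fisher_kpp", "allen_cahn", "pme_logistic"),
                             s = 0.5, x0 = 0) {
  kind <- match.arg(kind)
  if (kind == "allen_cahn") stopifnot(s > 0, s < 2)
  speed <- switch(kind, fisher_kpp = 2, allen_cahn = s, pme_logistic = 1)
  structure(list(kind = kind, speed = speed, sigma2 = 2, b = 0,
                 s = s, x0 = x0),
            class = "wave_frame_model")
}

#' @export
print.wave_frame_model <- function(x, ...) {
  cat(sprintf("<wave_frame_model: %s, c = %g>\n", x$kind, x$speed))
  invisible(x)
}

## cache for the numerically relaxed Fisher-KPP profile
.lrpop_cache <- new.env(parent = emptyenv())

#' Numerically relaxed minimal-speed Fisher-KPP profile table
#'
#' The minimal-speed profile is selected dynamically: a Heaviside initial
#' condition is relaxed in the frame co-moving at \eqn{c=2} until stationary,
#' then recentred so that \eqn{w(0) = 1/2}.  The table is cached per session.
#'
#' @param xlim domain of the relaxation.
#' @param dx grid spacing.
#' @param T relaxation horizon.
#' @return a list with \code{x} and \code{w}.
#' @export
fisher_kpp_profile_table <- function(xlim = c(-30, 30), dx = 0.05, T = 30) {
  key <- paste0("kpp_", xlim[1], "_", xlim[2], "_", dx, "_", T)
  if (!is.null(.lrpop_cache[[key]])) return(.lrpop_cache[[key]])
  x <- seq(xlim[1], xlim[2], by = dx)
  w <- as.numeric(x < 0)
  dt <- 0.38 * dx^2 / 2
  nstep <- ceiling(T / dt)
  n <- length(x)
  for (s in seq_len(nstep)) {
    ## co-moving frame: w_t = w_xx + 2 w_x + w(1-w), Dirichlet w(-inf)=1, w(inf)=0
    lap <- (c(w[-1], 0) - 2 * w + c(1, w[-n])) / dx^2
    adv <- 2 * (c(w[-1], 0) - w) / dx      # upwind for +2 w_x (wind to the left)
    w <- pmax(w + dt * (lap + adv + w * (1 - w)), 0)
    w[1] <- 1; w[n] <- 0
  }
  ## recentre at the half level
  xc <- front_position(list(x = x, values = w), 0.5)
  out <- list(x = x - xc, w = w)
  .lrpop_cache[[key]] <- out
  out
}

#' Travelling-wave profile
#'
#' Evaluates the wave profile \eqn{w} at \code{x} (in the wave frame, front
#' near the origin).  Closed forms for the Allen-Cahn and porous-medium
#' waves; interpolation in the relaxed table for Fisher-KPP.
#'
#' @param model a \code{\link{wave_frame_model}}.
#' @param x coordinates in the wave frame.
#' @return profile values in [0, 1].
#' @export
wave_profile <- function(model, x) {
  stopifnot(inherits(model, "wave_frame_model"))
  switch(model$kind,
    allen_cahn = 1 / (1 + exp(x)),
    pme_logistic = pmax(1 - exp((x - model$x0) / 2), 0),
    fisher_kpp = {
      tab <- fisher_kpp_profile_table()
      w <- stats::approx(tab$x, tab$w, xout = x, rule = 2)$y
      pmin(pmax(w, 0), 1)
    })
}

## analytic profile derivatives where closed forms exist
wave_profile_deriv <- function(model, x, order = 1L) {
  switch(model$kind,
    allen_cahn = {
      ex <- exp(x)
      if (order == 1L) -ex / (1 + ex)^2
      else ex * (ex - 1) / (1 + ex)^3
    },
    pme_logistic = {
      z <- x - model$x0
      d <- ifelse(z < 0, exp(z / 2), 0)
      if (order == 1L) -d / 2 else -d / 4
    },
    stop("no analytic derivatives for ", model$kind))
}

#' Residual of a profile in the co-moving travelling-wave ODE
#'
#' A travelling wave \eqn{w} with speed \eqn{c} satisfies
#' \eqn{r\,\mathcal{B}^*(\gamma w) + wF + c\,w' = 0} in the co-moving frame;
#' with the package's wave models (\eqn{\sigma^2=2}, \eqn{b=0}) this is
#' \eqn{(\gamma w)'' + wF(w) + c w' = 0}.  Returns the maximum absolute
#' residual over a grid.  Derivatives are analytic for the closed-form
#' profiles (\code{derivatives = "analytic"}) or central finite differences
#' (\code{"fd"}); the Fisher-KPP table only supports \code{"fd"}.
#'
#' @param model a \code{\link{wave_frame_model}}.
#' @param c wave speed (default: the model's own speed; pass another value to
#'   verify that wrong speeds are rejected).
#' @param x evaluation grid.  For the porous-medium wave the default grid
#'   stays strictly behind the front, where the profile is smooth.
#' @param derivatives \code{"analytic"} or \code{"fd"}.
#' @param dx finite-difference step for \code{derivatives = "fd"}.
#' @return maximum absolute residual.
#' @export
travelling_wave_residual <- function(model, c = model$speed, x = NULL,
                                     derivatives = c("analytic", "fd"),
                                     dx = 1e-3) {
  derivatives <- match.arg(derivatives)
  if (model$kind == "fisher_kpp") derivatives <- "fd"
  if (is.null(x)) {
    x <- switch(model$kind,
      pme_logistic = seq(-20, model$x0 - 1e-3, length.out = 2001),
      seq(-15, 15, length.out = 2001))
  }
  gw <- function(z) {   # gamma(w) * w in the wave frame
    w <- wave_profile(model, z)
    if (model$kind == "pme_logistic") w^2 else w
  }
  Ffun <- function(w) {
    if (model$kind == "allen_cahn") (1 - w) * (2 * w - 1 + model$s) else 1 - w
  }
  w <- wave_profile(model, x)
  if (derivatives == "analytic") {
    w1 <- wave_profile_deriv(model, x, 1L)
    w2 <- wave_profile_deriv(model, x, 2L)
    gw2 <- if (model$kind == "pme_logistic") 2 * (w1^2 + w * w2) else w2
    res <- gw2 + w * Ffun(w) + c * w1
  } else {
    gpp <- (gw(x + dx) - 2 * gw(x) + gw(x - dx)) / dx^2
    wp <- (wave_profile(model, x + dx) - wave_profile(model, x - dx)) / (2 * dx)
    res <- gpp + w * Ffun(w) + c * wp
  }
  max(abs(res))
}
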