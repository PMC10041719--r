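#' Carreau shear-thinning viscosity parameters
#'
#' Parameter set for the Carreau model
#' \deqn{\eta(\dot\gamma) = \eta_\infty + (\eta_0 - \eta_\infty)
#'       \left[1 + (\lambda\dot\gamma)^2\right]^{(n-1)/2}}
#' interpolating between the low-shear plateau `eta_0` and the high-shear
#' plateau `eta_inf`. Defaults are the standard literature values for whole
#' blood: `eta_inf = 3.45e-3`, `eta_0 = 5.6e-2` kg/(m s), `n = 0.3568`,
#' `lambda = 3.313` s.
#'
#' Setting `eta_0 = eta_inf` collapses the model to a Newtonian fluid, which
#' drives the solver's analytic (Poiseuille) validation mode.
#'
#' @param eta_inf High-shear (infinite-shear) viscosity, kg/(m s).
#' @param eta_0 Low-shear (zero-shear) viscosity, kg/(m s).
#' @param n Power-law index in `(0, 1]`.
#' @param lambda Relaxation time constant, s.
#' @return An object of class `carreau_params`.
#' @export
carreau_params <- function(eta_inf = 3.45e-3, eta_0 = 5.6e-2,
                           n = 0.3568, lambda = 3.313) {
  if (!(eta_inf > 0) || eta_0 < eta_inf) {
    stop("require eta_0 >= eta_inf > 0")
  }
  if (!(lambda > 0)) stop("`lambda` must be positive")
  if (!(n > 0 && n <= 1)) stop("`n` must be in (0, 1]")
  structure(list(eta_inf = eta_inf, eta_0 = eta_0, n = n, lambda = lambda),
            class = "carreau_params")
}

#' Newtonian parameter set
#'
#' Degenerate Carreau parameters with both plateaus equal to `mu`, giving a
#' constant viscosity for all shear rates.
#'
#' @param mu Constant dynamic viscosity, kg/(m s). Default is the blood
#'   high-shear plateau 3.45e-3.
#' @return A `carreau_params` object.
#' @export
newtonian_params <- function(mu = 3.45e-3) {
  carreau_params(eta_inf = mu, eta_0 = mu, n = 1, lambda = 1)
}

#' @export
print.carreau_params <- function(x, ...) {
  cat(sprintf(
    "<carreau_params> eta_inf=%.3g eta_0=%.3g kg/(m s), n=%.4g, lambda=%.4g s\n",
    x$eta_inf, x$eta_0, x$n, x$lambda))
  invisible(x)
}

#' Carreau viscosity
#'
#' Evaluates the Carreau law at shear rate(s) `gamma_dot`. Strictly
#' decreasing in the shear rate when `n < 1` and `eta_0 > eta_inf`, and
#' bounded in `[eta_inf, eta_0]`.
#'
#' @param gamma_dot Shear rate magnitude(s), 1/s, nonnegative.
#' @param params A [carreau_params()] object.
#' @return Dynamic viscosity, kg/(m s) (= Pa s), vectorized over `gamma_dot`.
#' @examples
#' carreau_viscosity(0, carreau_params())      # low-shear plateau 5.6e-2
#' carreau_viscosity(1e12, carreau_params())   # high-shear plateau
#' @export
carreau_viscosity <- function(gamma_dot, params = carreau_params()) {
  stopifnot(inherits(params, "carreau_params"))
  if (any(gamma_dot < 0)) stop("`gamma_dot` must be nonnegative")
  params$eta_inf + (params$eta_0 - params$eta_inf) *
    (1 + (params$lambda * gamma_dot)^2)^((params$n - 1) / 2)
}

#' Shear-rate magnitude from velocity gradients
#'
#' Second-invariant shear rate \eqn{\dot\gamma = \sqrt{2 D : D}} of the
#' rate-of-deformation tensor for axisymmetric flow `(u_x(x, r), u_r(x, r))`.
#' The hoop strain `u_r / r` must be supplied with its axis limit
#' `u_r / r -> du_r/dr` already applied on the axis (the solver does this
#' analytically rather than by clamping).
#'
#' For pure axial shear (`dux_dr = g`, all else zero) the result is `|g|`;
#' for rigid-body or uniform motion it is zero.
#'
#' @param dux_dx,dux_dr Gradients of the axial velocity, 1/s.
#' @param dur_dx,dur_dr Gradients of the radial velocity, 1/s.
#' @param ur_over_r Hoop strain `u_r / r` (limit `dur_dr` on the axis), 1/s.
#' @return Nonnegative shear rate, 1/s; vectorized (arrays keep their shape).
#' @export
shear_rate_magnitude <- function(dux_dx, dux_dr, dur_dx = 0, dur_dr = 0,
                                 ur_over_r = 0) {
  sqrt(2 * (dux_dx^2 + dur_dr^2 + ur_over_r^2) + (dux_dr + dur_dx)^2)
}
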