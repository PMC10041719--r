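#' Parametric axisymmetric stenosed-vessel geometry
#'
#' Constructs an idealized, rigid, axisymmetric vessel with a smooth
#' cosine-shaped constriction standing in for a stenosed left anterior
#' descending (LAD) coronary artery. Severity is the fractional *diameter*
#' reduction at the throat (the common angiographic convention): a severity
#' of 0.5 halves the local diameter, leaving a throat radius of
#' `(1 - severity) * inlet_radius`.
#'
#' The radius profile is
#' \deqn{R(x) = R_0 \left[1 - \frac{s}{2}\left(1 + \cos\frac{2\pi (x - x_c)}{\ell}\right)\right]}
#' inside the stenosis segment `|x - x_c| <= l/2` and `R_0` outside, which is
#' continuous with zero slope at both shoulders (C1 cross-sectional area).
#'
#' @param inlet_radius Inlet (reference) radius in meters. Default 1.5 mm,
#'   a typical proximal LAD lumen radius.
#' @param vessel_length Total axial length in meters. Default 30 mm.
#' @param stenosis_center Axial position of the throat in meters. Default 15 mm.
#' @param stenosis_length Axial extent of the constriction in meters.
#'   Default 10 mm.
#' @param severity Fractional diameter reduction at the throat, in `[0, 1)`.
#'
#' @return An object of class `stenosis_geometry`.
#' @examples
#' geo <- stenosis_geometry(severity = 0.5)
#' radius_profile(geo, geo$stenosis_center)  # == 0.5 * inlet_radius
#' @export
stenosis_geometry <- function(inlet_radius = 1.5e-3,
                              vessel_length = 30e-3,
                              stenosis_center = 15e-3,
                              stenosis_length = 10e-3,
                              severity = 0) {
  stopifnot(inlet_radius > 0, vessel_length > 0, stenosis_length > 0)
  if (!is.numeric(severity) || length(severity) != 1L || severity < 0 || severity >= 1) {
    stop("`severity` must be a single value in [0, 1)")
  }
  # stenosis strictly inside, with >= one inlet diameter of straight tube
  # on each side
  margin <- 2 * inlet_radius
  lo <- stenosis_center - stenosis_length / 2
  hi <- stenosis_center + stenosis_length / 2
  if (severity > 0 && (lo < margin || hi > vessel_length - margin)) {
    stop("stenosis segment must lie inside the vessel with at least one ",
         "inlet diameter of straight tube on each side")
  }
  structure(
    list(
      inlet_radius = inlet_radius,
      vessel_length = vessel_length,
      stenosis_center = stenosis_center,
      stenosis_length = stenosis_length,
      severity = severity
    ),
    class = "stenosis_geometry"
  )
}

#' @export
print.stenosis_geometry <- function(x, ...) {
  cat(sprintf(
    "<stenosis_geometry> severity %.0f%%: inlet radius %.3g mm, throat radius %.3g mm\n",
    100 * x$severity, 1e3 * x$inlet_radius,
    1e3 * (1 - x$severity) * x$inlet_radius
  ))
  cat(sprintf("  length %.3g mm, stenosis %.3g mm centered at %.3g mm\n",
              1e3 * x$vessel_length, 1e3 * x$stenosis_length,
              1e3 * x$stenosis_center))
  invisible(x)
}

#' Local vessel radius
#'
#' Evaluates the radius profile `R(x)` of a [stenosis_geometry()] at axial
#' positions `x`. Equals the inlet radius outside the stenosis segment and
#' attains its minimum `(1 - severity) * inlet_radius` exactly at the throat.
#'
#' @param geometry A `stenosis_geometry`.
#' @param x Axial position(s) in meters, inside `[0, vessel_length]`.
#' @return Radius (m), vectorized over `x`.
#' @export
radius_profile <- function(geometry, x) {
  stopifnot(inherits(geometry, "stenosis_geometry"))
  if (any(x < 0 | x > geometry$vessel_length)) {
    stop("`x` outside the vessel: must satisfy 0 <= x <= vessel_length")
  }
  r0 <- geometry$inlet_radius
  s <- geometry$severity
  xc <- geometry$stenosis_center
  l <- geometry$stenosis_length
  inside <- abs(x - xc) <= l / 2
  r <- rep(r0, length(x))
  r[inside] <- r0 * (1 - (s / 2) * (1 + cos(2 * pi * (x[inside] - xc) / l)))
  r
}

#' Axial derivative dR/dx of the radius profile
#'
#' Analytic slope of the cosine constriction; zero outside the stenosis
#' segment and at both shoulders. Used by the body-fitted grid metrics.
#'
#' @inheritParams radius_profile
#' @return dR/dx (dimensionless), vectorized over `x`.
#' @export
radius_slope <- function(geometry, x) {
  stopifnot(inherits(geometry, "stenosis_geometry"))
  if (any(x < 0 | x > geometry$vessel_length)) {
    stop("`x` outside the vessel: must satisfy 0 <= x <= vessel_length")
  }
  r0 <- geometry$inlet_radius
  s <- geometry$severity
  xc <- geometry$stenosis_center
  l <- geometry$stenosis_length
  inside <- abs(x - xc) <= l / 2
  dr <- numeric(length(x))
  dr[inside] <- r0 * (s / 2) * (2 * pi / l) * sin(2 * pi * (x[inside] - xc) / l)
  dr
}

#' Build the geometry for one severity case
#'
#' Convenience constructor used by the scenario bank: default LAD-like
#' dimensions (inlet radius 1.5 mm, length 30 mm, 10 mm stenosis centered at
#' 15 mm) with a given severity. Severities of 0.95 or more are refused
#' because the computational grid would degenerate at the throat.
#'
#' @param severity Fractional diameter reduction in `[0, 0.95)`. The
#'   standard sweep uses `{0.3, 0.4, 0.5, 0.6, 0.7, 0.8}`.
#' @param defaults Optional named list overriding `inlet_radius`,
#'   `vessel_length`, `stenosis_center`, `stenosis_length`.
#' @return A `stenosis_geometry`.
#' @export
build_scenario_geometry <- function(severity, defaults = list()) {
  if (severity >= 0.95) {
    stop("severity >= 0.95 refused: throat too narrow, grid would degenerate")
  }
  args <- utils::modifyList(
    list(inlet_radius = 1.5e-3, vessel_length = 30e-3,
         stenosis_center = 15e-3, stenosis_length = 10e-3),
    defaults
  )
  args$severity <- severity
  do.call(stenosis_geometry, args)
}
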