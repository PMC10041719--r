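#' Signed wall shear stress over the recorded cycle
#'
#' Computes the tangential wall shear stress at every wall station and
#' recorded instant from the near-wall tangential velocities stored in a
#' [solve_cycles()] record. The one-sided wall-normal derivative is second
#' order (quadratic through the no-slip wall value and the two nearest
#' radial stations), and the wall viscosity is the Carreau viscosity
#' evaluated at the wall shear rate. In the axisymmetric setting the WSS
#' vector reduces to a signed scalar: positive values mean
#' downstream-directed traction.
#'
#' The series covers exactly the final recorded period (both endpoints).
#'
#' @param record A `steno_record` from [solve_cycles()].
#' @param rheology A [carreau_params()] set; defaults to the record's
#'   scenario rheology.
#' @return An object of class `steno_wss`: wall station positions `x` (m),
#'   relative sample `times` (s), `period`, and the `wss` matrix
#'   (stations x samples, Pa).
#' @export
wall_shear_stress <- function(record, rheology = record$scenario$rheology) {
  stopifnot(inherits(record, "steno_record"),
            inherits(rheology, "carreau_params"))
  T <- record$period
  tmax <- max(record$times)
  if (tmax - min(record$times) < T - 1e-9) {
    stop("record does not cover a full period; cannot form a wall-shear series")
  }
  sel <- which(record$times >= tmax - T - 1e-9)
  g <- record$grid
  # d(u_t)/ds at the wall (s = distance from the wall into the fluid):
  # sqrt(1 + R'^2)/R * (9 u1 - u2) / (3 deta)
  fac <- sqrt(1 + g$Rpc^2) / (radius_profile(g$geometry, g$xc) * 3 * g$deta)
  duds <- fac * (9 * record$wall_ut1[, sel, drop = FALSE] -
                   record$wall_ut2[, sel, drop = FALSE])
  mu_w <- carreau_viscosity(abs(duds), rheology)
  structure(
    list(x = g$xc, times = record$times[sel] - record$times[sel[1L]],
         period = T, wss = mu_w * duds),
    class = "steno_wss"
  )
}

#' @export
print.steno_wss <- function(x, ...) {
  cat(sprintf(
    "<steno_wss> %d wall stations x %d samples over %.3g s; |WSS| max %.3g Pa\n",
    nrow(x$wss), ncol(x$wss), x$period, max(abs(x$wss))))
  invisible(x)
}

.trapz_weights <- function(t) {
  n <- length(t)
  w <- numeric(n)
  w[1L] <- (t[2L] - t[1L]) / 2
  w[n] <- (t[n] - t[n - 1L]) / 2
  if (n > 2L) w[2:(n - 1L)] <- (t[3:n] - t[1:(n - 2L)]) / 2
  w
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' Trapezoidal time average of `|WSS|` over one period, per wall station.
#'
#' @param series A [wall_shear_stress()] series, or a plain matrix/vector of
#'   signed WSS samples with attribute-free uniform sampling over one period.
#' @param times,period Sampling times and period when `series` is not a
#'   `steno_wss` object.
#' @return Nonnegative TAWSS per station, Pa.
#' @export
tawss <- function(series, times = NULL, period = NULL) {
  s <- .as_wss(series, times, period)
  drop(abs(s$wss) %*% .trapz_weights(s$times)) / s$period
}

#' Oscillatory shear index (OSI)
#'
#' \deqn{OSI = 0.5\left[1 - \frac{|\int_0^T WSS\,dt|}{\int_0^T |WSS|\,dt}\right]}
#' per wall station: 0 for unidirectional shear, 0.5 for zero-mean
#' (perfectly oscillatory) shear. Stations with identically zero WSS are
#' assigned OSI = 0 by convention (avoiding a spurious 0/0 = 0.5 at
#' separation points with vanishing stress).
#'
#' @inheritParams tawss
#' @return OSI per station, in `[0, 0.5]`.
#' @export
osi <- function(series, times = NULL, period = NULL) {
  s <- .as_wss(series, times, period)
  w <- .trapz_weights(s$times)
  num <- abs(drop(s$wss %*% w))
  den <- drop(abs(s$wss) %*% w)
  out <- ifelse(den > 0, 0.5 * (1 - num / den), 0)
  pmin(pmax(out, 0), 0.5)
}

.as_wss <- function(series, times, period) {
  if (inherits(series, "steno_wss")) return(series)
  wss <- if (is.matrix(series)) series else matrix(series, nrow = 1L)
  if (is.null(times)) times <- seq(0, 1, length.out = ncol(wss))
  if (is.null(period)) period <- max(times) - min(times)
  if (max(times) - min(times) < period - 1e-9) {
    stop("samples do not cover a full period")
  }
  list(wss = wss, times = times, period = period)
}

#' Relative residence time (RRT)
#'
#' \deqn{RRT = [(1 - 2 \, OSI) \times TAWSS]^{-1}} in 1/Pa, a surrogate for
#' near-wall residence: large where the shear is weak and oscillatory. As
#' OSI approaches 0.5 (or TAWSS approaches 0) RRT diverges; values beyond
#' `ceiling` are capped at this documented sentinel.
#'
#' @param tawss_value TAWSS, Pa (>= 0); vectorized.
#' @param osi_value OSI in `[0, 0.5]`; vectorized.
#' @param ceiling Sentinel cap for the diverging limit, 1/Pa.
#' @return RRT per station, 1/Pa, in `(0, ceiling]`.
#' @export
rrt <- function(tawss_value, osi_value, ceiling = 1e9) {
  if (any(tawss_value < 0)) stop("`tawss_value` must be nonnegative")
  if (any(osi_value < 0 | osi_value > 0.5)) {
    stop("`osi_value` must lie in [0, 0.5]")
  }
  den <- (1 - 2 * osi_value) * tawss_value
  ifelse(den > 1 / ceiling, 1 / den, ceiling)
}

#' Wall index maps: TAWSS, OSI and RRT per station
#'
#' Convenience wrapper computing the wall-shear series and all three
#' hemodynamic wall indices from a record, with global peak values and
#' their axial locations attached.
#'
#' @param record A `steno_record`.
#' @param rheology Carreau parameters (defaults to the scenario's).
#' @param rrt_ceiling Sentinel cap passed to [rrt()].
#' @return A data frame of class `steno_index_maps` with columns `x`,
#'   `tawss`, `osi`, `rrt`; peak values and locations in
#'   `attr(, "peaks")`.
#' @export
index_maps <- function(record, rheology = record$scenario$rheology,
                       rrt_ceiling = 1e9) {
  s <- wall_shear_stress(record, rheology)
  ta <- tawss(s)
  os <- osi(s)
  rr <- rrt(ta, os, ceiling = rrt_ceiling)
  out <- data.frame(x = s$x, tawss = ta, osi = os, rrt = rr)
  class(out) <- c("steno_index_maps", "data.frame")
  finite <- rr < rrt_ceiling
  attr(out, "peaks") <- list(
    tawss = max(ta), tawss_x = s$x[which.max(ta)],
    osi = max(os), osi_x = s$x[which.max(os)],
    rrt = if (any(finite)) max(rr[finite]) else rrt_ceiling,
    rrt_x = s$x[which.max(ifelse(finite, rr, -Inf))],
    wss_instantaneous = max(abs(s$wss))
  )
  out
}

# linear interpolation of a stations x samples matrix at axial position x
.interp_axis <- function(A, xc, x) {
  if (x <= xc[1L]) return(A[1L, ])
  n <- length(xc)
  if (x >= xc[n]) return(A[n, ])
  i <- findInterval(x, xc)
  w <- (x - xc[i]) / (xc[i + 1L] - xc[i])
  (1 - w) * A[i, ] + w * A[i + 1L, ]
}

#' Probe-point pressure and velocity time series
#'
#' Extracts anterior (throat minus `probe_offset`), center (throat) and
#' posterior (throat plus `probe_offset`) monitoring points on the vessel
#' axis: pressures relative to the scenario outlet pressure, axis velocity
#' magnitudes, and the pairwise pressure differences. The default offset is
#' one inlet diameter.
#'
#' @param record A `steno_record`.
#' @param geometry Geometry (defaults to the record's).
#' @param probe_offset Axial distance of the anterior/posterior probes from
#'   the throat, m.
#' @return A data frame of class `steno_probes` with columns `time`,
#'   `p_anterior`, `p_center`, `p_posterior` (Pa, relative to outlet),
#'   `u_anterior`, `u_center`, `u_posterior` (m/s), `dp_anterior_posterior`
#'   and `dp_center_posterior` (Pa).
#' @export
probe_series <- function(record, geometry = record$scenario$geometry,
                         probe_offset = 2 * geometry$inlet_radius) {
  stopifnot(inherits(record, "steno_record"))
  xt <- geometry$stenosis_center
  xs <- c(anterior = xt - probe_offset, center = xt, posterior = xt + probe_offset)
  if (any(xs < 0 | xs > geometry$vessel_length)) {
    stop("probe_offset places a probe outside the vessel")
  }
  pout <- record$scenario$outlet_pressure
  xc <- record$grid$xc
  p <- lapply(xs, function(x) .interp_axis(record$axis_p, xc, x) - pout)
  u <- lapply(xs, function(x) abs(.interp_axis(record$axis_u, xc, x)))
  out <- data.frame(
    time = record$times,
    p_anterior = p$anterior, p_center = p$center, p_posterior = p$posterior,
    u_anterior = u$anterior, u_center = u$center, u_posterior = u$posterior
  )
  out$dp_anterior_posterior <- out$p_anterior - out$p_posterior
  out$dp_center_posterior <- out$p_center - out$p_posterior
  class(out) <- c("steno_probes", "data.frame")
  attr(out, "probe_x") <- xs
  out
}

#' Severity sweep summary table
#'
#' One row per scenario: peak anterior-minus-posterior probe pressure
#' difference, peak center (throat) velocity, peak wall TAWSS, maximum OSI
#' and maximum finite RRT, each with the in-cycle time (or axial position)
#' at which it occurs; sorted by severity.
#'
#' @param cases A list where each element has components `severity`,
#'   `maps` (a [index_maps()] result) and `probes` (a [probe_series()]
#'   result), as produced by [run_scenario()].
#' @return A data frame sorted by severity.
#' @export
severity_summary <- function(cases) {
  if (length(cases) < 1L) stop("need at least one scenario case")
  rows <- lapply(cases, function(cs) {
    pk <- attr(cs$maps, "peaks")
    pr <- cs$probes
    i_dp <- which.max(pr$dp_anterior_posterior)
    i_u <- which.max(pr$u_center)
    data.frame(
      severity = cs$severity,
      peak_probe_dp = pr$dp_anterior_posterior[i_dp],
      peak_probe_dp_time = pr$time[i_dp],
      peak_center_velocity = pr$u_center[i_u],
      peak_center_velocity_time = pr$time[i_u],
      peak_tawss = pk$tawss,
      peak_tawss_x = pk$tawss_x,
      max_osi = pk$osi,
      max_finite_rrt = pk$rrt
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$severity), , drop = FALSE]
  rownames(out) <- NULL
  out
}
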