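#' Body-fitted structured grid over a stenosed vessel
#'
#' Generates a structured axisymmetric grid in mapped coordinates
#' `(xi, eta)` with `xi = x` (uniform axial spacing) and `eta = r / R(x)`
#' (uniform in `[0, 1]`), so the outermost radial node follows the local
#' vessel radius exactly. Velocities and pressure are stored on a staggered
#' (MAC-type) arrangement in the mapped rectangle; the returned object also
#' carries the metric factors (`R`, `dR/dx` at faces and centers) needed for
#' the mapped-coordinate discretization.
#'
#' `axial_nodes` and `radial_nodes` count *cells*; there are
#' `axial_nodes + 1` axial stations (faces). Refining by an integer factor
#' nests the coarser grid's axial stations.
#'
#' @param geometry A [stenosis_geometry()].
#' @param axial_nodes Number of axial cells (>= 8).
#' @param radial_nodes Number of radial cells (>= 8).
#' @return An object of class `steno_grid`.
#' @examples
#' g <- generate_grid(stenosis_geometry(severity = 0.5), 60, 16)
#' @export
generate_grid <- function(geometry, axial_nodes, radial_nodes) {
  stopifnot(inherits(geometry, "stenosis_geometry"))
  nx <- as.integer(axial_nodes)
  nr <- as.integer(radial_nodes)
  if (nx < 8L || nr < 8L) stop("node counts must be >= 8 in each direction")
  # refuse degenerate throats: require the throat diameter to be resolved by
  # at least 4 cells of inlet-equivalent size
  if (nr * (1 - geometry$severity) < 4 - 1e-9) {
    stop(sprintf(
      "grid degenerate at the throat: %d radial cells leave fewer than 4 ",
      nr), "inlet-equivalent cells across the throat; increase radial_nodes")
  }
  L <- geometry$vessel_length
  dxi <- L / nx
  deta <- 1 / nr
  xf <- seq(0, L, length.out = nx + 1L)        # axial faces / stations
  xc <- 0.5 * (xf[-1L] + xf[-(nx + 1L)])       # axial cell centers
  etaf <- seq(0, 1, length.out = nr + 1L)      # radial faces (eta)
  etac <- 0.5 * (etaf[-1L] + etaf[-(nr + 1L)]) # radial centers (eta)

  g <- list(
    geometry = geometry,
    nx = nx, nr = nr,
    dxi = dxi, deta = deta,
    xf = xf, xc = xc, etaf = etaf, etac = etac,
    Rf = radius_profile(geometry, xf),
    Rc = radius_profile(geometry, xc),
    Rpf = radius_slope(geometry, xf),
    Rpc = radius_slope(geometry, xc)
  )
  # wall-adjacent cell index: each axial cell i maps to wall station xc[i]
  g$wall_node_index <- seq_len(nx)
  class(g) <- "steno_grid"
  g
}

#' @export
print.steno_grid <- function(x, ...) {
  cat(sprintf("<steno_grid> %d x %d cells over %.3g mm, severity %.0f%%\n",
              x$nx, x$nr, 1e3 * x$geometry$vessel_length,
              100 * x$geometry$severity))
  invisible(x)
}

#' Refine a grid by an integer factor
#'
#' Doubling (factor 2) both node counts nests the coarser grid's axial
#' stations exactly, which the grid-independence study relies on.
#'
#' @param grid A `steno_grid`.
#' @param factor Positive integer refinement factor.
#' @return A finer `steno_grid` over the same geometry.
#' @export
refine_grid <- function(grid, factor = 2L) {
  stopifnot(inherits(grid, "steno_grid"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be a positive integer")
  generate_grid(grid$geometry, grid$nx * factor, grid$nr * factor)
}

#' Node coordinates of a grid
#'
#' Physical `(x, r)` coordinates of the `(nx + 1) x (nr + 1)` structured
#' nodes, with the outermost radial node on the vessel wall.
#'
#' @param grid A `steno_grid`.
#' @return A list with matrices `x` and `r`, each `(nx + 1) x (nr + 1)`.
#' @export
grid_nodes <- function(grid) {
  stopifnot(inherits(grid, "steno_grid"))
  x <- matrix(grid$xf, grid$nx + 1L, grid$nr + 1L)
  r <- outer(grid$Rf, grid$etaf)
  list(x = x, r = r)
}
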