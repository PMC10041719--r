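#' Write a legacy-VTK structured grid snapshot
#'
#' Serializes the body-fitted grid -- optionally with a flow-field snapshot
#' and/or wall index maps -- as an ASCII legacy VTK `STRUCTURED_GRID`
#' (`(nx+1) x (nr+1) x 1` points in the meridional plane, axial x and
#' radial r as the first two coordinates). Velocities and pressure are
#' interpolated from the staggered layout to the nodes. Wall index maps
#' (`TAWSS`, `OSI`, `RRT`) are attached as point-data arrays replicated
#' along the radial direction so they paint the wall line in any VTK
#' viewer.
#'
#' @param path Output file path (conventionally `.vtk`).
#' @param grid A [generate_grid()] grid.
#' @param field Optional `steno_field` (or a list with `u`, `v`, `p`).
#' @param maps Optional [index_maps()] result.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(path, grid, field = NULL, maps = NULL) {
  stopifnot(inherits(grid, "steno_grid"))
  nx <- grid$nx; nr <- grid$nr
  nodes <- grid_nodes(grid)
  np <- (nx + 1L) * (nr + 1L)

  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  num <- function(x) format(x, digits = 9, trim = TRUE, scientific = TRUE)

  w("# vtk DataFile Version 3.0")
  w("stenoflow axisymmetric snapshot (x, r) plane")
  w("ASCII")
  w("DATASET STRUCTURED_GRID")
  w("DIMENSIONS %d %d 1", nx + 1L, nr + 1L)
  w("POINTS %d double", np)
  writeLines(paste(num(as.vector(nodes$x)), num(as.vector(nodes$r)), "0"), con)

  have_field <- !is.null(field)
  have_maps <- !is.null(maps)
  if (!have_field && !have_maps) return(invisible(path))

  w("POINT_DATA %d", np)
  if (have_field) {
    # interpolate staggered components to nodes
    un <- matrix(0, nx + 1L, nr + 1L)  # u at x-faces x eta-centers
    un[, 2:nr] <- 0.5 * (field$u[, 1:(nr - 1L)] + field$u[, 2:nr])
    un[, 1L] <- .axis_value(field$u[, 1L], field$u[, 2L])
    un[, nr + 1L] <- 0                          # no-slip wall
    vn <- matrix(0, nx + 1L, nr + 1L)  # v at x-centers x eta-faces
    vn[2:nx, ] <- 0.5 * (field$v[1:(nx - 1L), ] + field$v[2:nx, ])
    vn[1L, ] <- field$v[1L, ]
    vn[nx + 1L, ] <- field$v[nx, ]
    pn <- matrix(0, nx + 1L, nr + 1L)
    pc <- field$p
    # cell centers -> nodes by averaging the adjacent cells (clamped edges)
    ic <- pmin(pmax(rep(seq_len(nx + 1L) - 1L, nr + 1L), 1L), nx)
    ic2 <- pmin(pmax(rep(seq_len(nx + 1L), nr + 1L), 1L), nx)
    jc <- pmin(pmax(rep(seq_len(nr + 1L) - 1L, each = nx + 1L), 1L), nr)
    jc2 <- pmin(pmax(rep(seq_len(nr + 1L), each = nx + 1L), 1L), nr)
    pn[] <- 0.25 * (pc[cbind(ic, jc)] + pc[cbind(ic2, jc)] +
                      pc[cbind(ic, jc2)] + pc[cbind(ic2, jc2)])
    w("VECTORS velocity double")
    writeLines(paste(num(as.vector(un)), num(as.vector(vn)), "0"), con)
    w("SCALARS pressure double 1")
    w("LOOKUP_TABLE default")
    writeLines(num(as.vector(pn)), con)
  }
  if (have_maps) {
    for (nm in c("tawss", "osi", "rrt")) {
      vals <- stats::approx(maps$x, maps[[nm]], xout = grid$xf, rule = 2)$y
      w("SCALARS %s double 1", toupper(nm))
      w("LOOKUP_TABLE default")
      writeLines(num(rep(vals, nr + 1L)), con)
    }
  }
  invisible(path)
}
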