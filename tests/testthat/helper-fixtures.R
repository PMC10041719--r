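# Shared fixtures: small, fast scenario/grid combinations used across tests.

# straight rigid tube with a constant pressure drop, Newtonian blood
poiseuille_scenario <- function(dp = 100, mu = 3.45e-3,
                                nx = 64L, nr = 16L, pout = 7329) {
  geo <- stenosis_geometry(severity = 0)
  scenario(0,
           geometry = geo,
           inlet_waveform = synthesize_inlet_waveform(pout + dp, 0),
           outlet_pressure = pout,
           rheology = newtonian_params(mu),
           solver = solver_config(grid_nx = nx, grid_nr = nr))
}

# coarse stenosed scenario for quick pulsatile runs
coarse_scenario <- function(severity = 0.5, nx = 90L, nr = 20L,
                            cycles = 2L, discard = 1L, samples = 50L) {
  scenario(severity,
           solver = solver_config(grid_nx = nx, grid_nr = nr,
                                  cycles_total = cycles,
                                  cycles_discarded = discard,
                                  samples_per_cycle = samples))
}

# analytic Poiseuille quantities for a tube of radius R, length L
poiseuille_exact <- function(dp, R, L, mu) {
  list(u_center = dp * R^2 / (4 * mu * L),
       flux = pi * dp * R^4 / (8 * mu * L),
       wall_shear = dp * R / (2 * L))
}

# quadratic axis extrapolation used on staggered fields in several tests
axis_extrap <- function(f1, f2) (9 * f1 - f2) / 8

# minimal hand-built record carrying wall extracts, for index-module tests
# that need full control of the near-wall signal
synthetic_record <- function(ut1, ut2, times, grid, scenario,
                             axis_p = NULL, axis_u = NULL) {
  nx <- grid$nx
  M <- length(times)
  if (is.null(axis_p)) axis_p <- matrix(0, nx, M)
  if (is.null(axis_u)) axis_u <- matrix(0, nx, M)
  structure(
    list(times = times, period = scenario$inlet_waveform$period,
         axis_u = axis_u, axis_p = axis_p,
         wall_ut1 = ut1, wall_ut2 = ut2,
         flux_in = numeric(M), flux_out = numeric(M),
         outlet_umax = numeric(M),
         grid = grid, scenario = scenario),
    class = "steno_record"
  )
}
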