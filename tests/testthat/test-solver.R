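test_that("quiescent state with equal pressures is preserved exactly", {
  geo <- stenosis_geometry(severity = 0)
  wf <- synthesize_inlet_waveform(8000, 0)
  sc <- scenario(0, geometry = geo, inlet_waveform = wf,
                 outlet_pressure = 8000,
                 solver = solver_config(grid_nx = 24, grid_nr = 8))
  ctx <- solver_context(sc, generate_grid(geo, 24, 8))
  f <- new_flow_field(ctx)
  f2 <- advance_step(f, sc, ctx = ctx)
  expect_equal(max(abs(f2$u)), 0)
  expect_equal(max(abs(f2$v)), 0)
  expect_equal(max(f2$p) - min(f2$p), 0, tolerance = 1e-9)
  expect_equal(f2$time, sc$solver$time_step)
})

test_that("a time step violating the stability bound is refused", {
  sc <- poiseuille_scenario(nx = 32L, nr = 8L)
  sc$solver$time_step <- 0.5
  ctx <- solver_context(sc, generate_grid(sc$geometry, 32L, 8L))
  f <- new_flow_field(ctx)
  expect_error(advance_step(f, sc, ctx = ctx), "CFL")
})

test_that("transient solve converges to Poiseuille flow in Newtonian mode", {
  mu <- 3.45e-3; dp <- 100
  sc <- poiseuille_scenario(dp = dp, mu = mu, nx = 96L, nr = 24L)
  g <- generate_grid(sc$geometry, 96L, 24L)
  st <- steady_solve(sc, grid = g, max_time = 1.2)
  expect_true(st$converged)
  ex <- poiseuille_exact(dp, 1.5e-3, 30e-3, mu)
  # centerline velocity via quadratic axis extrapolation at mid-tube
  u_axis <- axis_extrap(st$field$u[49, 1], st$field$u[49, 2])
  expect_equal(u_axis, ex$u_center, tolerance = 0.02)
  expect_equal(st$flux_out, ex$flux, tolerance = 0.02)
  # discrete mass conservation: flux identical through every cross-section
  expect_equal(st$flux_in, st$flux_out, tolerance = 5e-3)
  # parabolic profile shape at the outlet-adjacent interior station
  eta <- g$etac
  u_profile <- st$field$u[72, ]
  expect_equal(u_profile / max(u_profile),
               (1 - eta^2) / max(1 - eta^2), tolerance = 0.02)
})

test_that("pulsatile records conserve mass and satisfy the residual tolerance", {
  sc <- coarse_scenario(0.5, nx = 60L, nr = 16L, cycles = 2L, discard = 1L,
                        samples = 25L)
  # drift is measured against the from-rest spin-up cycle here; harmless
  rec <- suppressWarnings(solve_cycles(sc))
  expect_true(all(rec$residual_log$continuity_residual <= 1e-4 + 1e-12))
  # inlet and outlet flux agree within 0.5% at peak flow
  ipk <- which.max(abs(rec$flux_out))
  expect_equal(rec$flux_in[ipk], rec$flux_out[ipk], tolerance = 5e-3)
  # sample times strictly increasing and covering one period after discard
  expect_true(all(diff(rec$times) > 0))
  expect_gte(max(rec$times) - min(rec$times), rec$period - 1e-9)
})

test_that("solver runs are bitwise deterministic", {
  sc <- coarse_scenario(0.6, nx = 48L, nr = 16L, cycles = 1L, discard = 0L,
                        samples = 10L)
  r1 <- suppressWarnings(solve_cycles(sc))
  r2 <- suppressWarnings(solve_cycles(sc))
  expect_identical(r1$axis_u, r2$axis_u)
  expect_identical(r1$axis_p, r2$axis_p)
  expect_identical(r1$wall_ut1, r2$wall_ut1)
})

test_that("single-cycle runs warn that periodicity cannot be verified", {
  sc <- coarse_scenario(0.5, nx = 48L, nr = 16L, cycles = 1L, discard = 0L,
                        samples = 10L)
  expect_warning(solve_cycles(sc), "periodicity")
})

test_that("one extra viscosity Picard iteration changes the step only mildly", {
  sc <- coarse_scenario(0.6, nx = 48L, nr = 16L, cycles = 1L, discard = 0L,
                        samples = 5L)
  ctx <- solver_context(sc, generate_grid(sc$geometry, 48L, 16L))
  f <- new_flow_field(ctx)
  for (i in 1:30) f <- stenoflow:::.step(f, ctx, 2e-4, sc$solver)
  cfg2 <- sc$solver; cfg2$viscosity_iters <- 2L
  f1 <- stenoflow:::.step(f, ctx, 2e-4, sc$solver)
  f2 <- stenoflow:::.step(f, ctx, 2e-4, cfg2)
  rel <- max(abs(f1$u - f2$u)) / max(abs(f1$u))
  expect_lt(rel, 0.02)
  expect_gt(rel, 0)  # the modes are genuinely different
})

test_that("grid ladder bookkeeping: identical grids and nesting checks", {
  sc <- poiseuille_scenario(nx = 48L, nr = 12L)
  g <- generate_grid(sc$geometry, 48L, 12L)
  out <- grid_independence_study(sc, grids = list(g, g, g))
  expect_equal(out$rel_change[-1], c(0, 0))
  expect_identical(attr(out, "converged_level"), 2L)
  g2 <- generate_grid(sc$geometry, 72L, 18L)
  expect_error(grid_independence_study(sc, grids = list(g, g2, g2)),
               "nested")
})
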