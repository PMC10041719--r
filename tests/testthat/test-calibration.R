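# calibration runs use deliberately small grids and single cycles: the
# bisection/secant mechanics are grid-agnostic

cal_config <- function(sc) {
  cfg <- sc$solver
  cfg$cycles_total <- 1L
  cfg$cycles_discarded <- 0L
  cfg$samples_per_cycle <- 25L
  cfg
}

test_that("calibrating to the already-produced response is a fixed point", {
  sc <- coarse_scenario(0.5, nx = 48L, nr = 16L)
  g <- generate_grid(sc$geometry, 48L, 16L)
  cfg <- cal_config(sc)
  rec <- suppressWarnings(solve_cycles(sc, cfg, g))
  dp0 <- max(probe_series(rec)$dp_anterior_posterior)
  cal <- calibrate_inlet_waveform(sc, dp0, metric = "peak_probe_dp",
                                  grid = g, config = cfg)
  info <- attr(cal, "calibration")
  expect_equal(info$beta, 1, tolerance = 1e-9)
  expect_identical(nrow(info$iterations), 1L)
})

test_that("larger targets calibrate to larger drive scales, closing the loop", {
  sc <- coarse_scenario(0.5, nx = 48L, nr = 16L)
  g <- generate_grid(sc$geometry, 48L, 16L)
  cfg <- cal_config(sc)
  cal_lo <- calibrate_inlet_waveform(sc, 40, metric = "peak_probe_dp",
                                     grid = g, config = cfg)
  cal_hi <- calibrate_inlet_waveform(sc, 120, metric = "peak_probe_dp",
                                     grid = g, config = cfg)
  b_lo <- attr(cal_lo, "calibration")$beta
  b_hi <- attr(cal_hi, "calibration")$beta
  expect_gt(b_hi, b_lo)
  # closed loop: re-simulating the calibrated scenario reproduces the target
  rec <- suppressWarnings(solve_cycles(cal_hi, cfg, g))
  dp <- max(probe_series(rec)$dp_anterior_posterior)
  expect_equal(dp, 120, tolerance = 0.02)
})

test_that("amplitude-only calibration refuses targets below the mean-drive floor", {
  # with the full clinical mean drive, the transstenotic dP floor at zero
  # pulse amplitude far exceeds 10 Pa
  sc <- scenario(0.8, calibrated_defaults = FALSE,
                 solver = solver_config(grid_nx = 48L, grid_nr = 20L))
  g <- generate_grid(sc$geometry, 48L, 20L)
  expect_error(
    calibrate_inlet_amplitude(sc, 10, grid = g, config = cal_config(sc)),
    "calibration failure")
})
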