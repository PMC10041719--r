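test_that("waveform honors mean, peak location and periodicity contracts", {
  wf <- synthesize_inlet_waveform(9000, 1500)
  s <- wf$samples
  expect_true(all(diff(s$time) > 0))
  expect_identical(s$time[1], 0)
  expect_identical(s$time[nrow(s)], wf$period)
  # periodic endpoints
  expect_equal(s$pressure[1], s$pressure[nrow(s)], tolerance = 1e-9)
  # argmax at the systolic peak
  expect_equal(s$time[which.max(s$pressure)], 0.4)
  expect_equal(max(s$pressure), 9000 + 1500, tolerance = 1e-9)
  # trapezoidal time-average oracle: within 0.1% of the stated mean
  tm <- seq(0, wf$period, length.out = 4001)
  p <- waveform_pressure(wf, tm)
  integral <- sum((p[-1] + p[-length(p)]) / 2 * diff(tm))
  expect_equal(integral / wf$period, 9000, tolerance = 9 / 9000)

  # zero amplitude: constant
  wf0 <- synthesize_inlet_waveform(8000, 0)
  expect_equal(wf0$samples$pressure, rep(8000, nrow(wf0$samples)))

  expect_error(synthesize_inlet_waveform(9000, 1500, n_samples = 8), ">= 16")
  expect_error(synthesize_inlet_waveform(9000, -5), ">= 0")
  expect_error(synthesize_inlet_waveform(9000, 10, systolic_peak_time = 0.9,
                                         period = 0.8), "peak_time")
})

test_that("waveform synthesis is deterministic and rescales about a reference", {
  a <- synthesize_inlet_waveform(9300, 1500)
  b <- synthesize_inlet_waveform(9300, 1500)
  expect_identical(a$samples$pressure, b$samples$pressure)

  sc <- scale_waveform(a, 0.25, 7229)
  expect_equal(sc$mean_pressure, 7229 + 0.25 * (9300 - 7229))
  expect_equal(sc$pulse_amplitude, 0.25 * 1500)
  expect_equal(sc$period, a$period)
})

test_that("the six printed outlet pressures are exact and others refuse", {
  printed <- c(8843, 8041, 7819, 7446, 7377, 7229)
  sev <- c(0.3, 0.4, 0.5, 0.6, 0.7, 0.8)
  for (i in seq_along(sev)) {
    expect_identical(outlet_pressure_for(sev[i]), printed[i])
  }
  expect_error(outlet_pressure_for(0.45), "supply your own")
  expect_error(outlet_pressure_for(0.85), "supply your own")
})

test_that("FFR surrogate is the scale-invariant pressure ratio", {
  expect_identical(compute_ffr(9000, 9000), 1)
  expect_identical(compute_ffr(0, 9000), 0)
  expect_equal(compute_ffr(7229, 9500), 0.761, tolerance = 1e-3)
  for (k in c(0.5, 2, 133.32)) {
    expect_equal(compute_ffr(k * 7229, k * 9500), compute_ffr(7229, 9500))
  }
  expect_error(compute_ffr(7000, 0), "positive")
})

test_that("scenario bank carries the clinical pressures and defaults", {
  bank <- scenario_bank()
  expect_length(bank, 6)
  expect_identical(
    vapply(bank, `[[`, numeric(1), "outlet_pressure"),
    c(s30 = 8843, s40 = 8041, s50 = 7819, s60 = 7446, s70 = 7377, s80 = 7229))
  expect_true(all(vapply(bank, `[[`, numeric(1), "density") == 1060))
  for (sc in bank) {
    expect_s3_class(sc$geometry, "stenosis_geometry")
    expect_identical(sc$solver$residual_tolerance, 1e-4)
    expect_identical(sc$rheology$lambda, 3.313)
  }
  expect_error(scenario(0.5, outlet_pressure = -10), "positive")
})
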