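test_that("radius profile follows the cosine constriction", {
  r0 <- 1.5e-3
  geo0 <- stenosis_geometry(severity = 0)
  x <- seq(0, geo0$vessel_length, length.out = 17)
  expect_equal(radius_profile(geo0, x), rep(r0, 17))

  geo5 <- stenosis_geometry(severity = 0.5)
  expect_equal(radius_profile(geo5, geo5$stenosis_center), 0.5 * r0)

  # quarter point of the cosine bump: cos(+-pi/2) = 0
  geo8 <- stenosis_geometry(severity = 0.8)
  xq <- geo8$stenosis_center + c(-1, 1) * geo8$stenosis_length / 4
  expect_equal(radius_profile(geo8, xq), rep(0.6 * r0, 2), tolerance = 1e-12)

  # continuous and flat at the shoulders, inlet radius outside
  sh <- geo8$stenosis_center + geo8$stenosis_length / 2
  expect_equal(radius_profile(geo8, sh), r0, tolerance = 1e-12)
  expect_equal(radius_slope(geo8, sh), 0, tolerance = 1e-12)
  expect_equal(radius_slope(geo8, sh + 1e-4), 0)

  expect_error(radius_profile(geo8, -1e-4), "outside")
  expect_error(radius_profile(geo8, geo8$vessel_length + 1e-6), "outside")
})

test_that("throat diameter ratio equals 1 - severity for any severity", {
  for (s in c(0, 0.1, 0.3, 0.5, 0.62, 0.8, 0.9)) {
    geo <- stenosis_geometry(severity = s)
    rt <- radius_profile(geo, geo$stenosis_center)
    expect_equal(rt / geo$inlet_radius, 1 - s, tolerance = 1e-14)
    # minimum is attained exactly at the throat
    x <- seq(0, geo$vessel_length, length.out = 301)
    expect_gte(min(radius_profile(geo, x)), rt - 1e-15)
  }
})

test_that("scenario geometry defaults and refusals", {
  expect_equal(radius_profile(build_scenario_geometry(0.3), 15e-3), 0.7 * 1.5e-3)
  expect_equal(radius_profile(build_scenario_geometry(0.8), 15e-3), 0.2 * 1.5e-3)
  g6 <- build_scenario_geometry(0.6)
  expect_equal(radius_profile(g6, g6$stenosis_center), 0.6e-3)
  expect_error(build_scenario_geometry(0.95), "degenerate")
  expect_error(stenosis_geometry(severity = 1.0), "severity")
  # stenosis must keep a straight margin on both sides
  expect_error(stenosis_geometry(severity = 0.5, stenosis_center = 4e-3),
               "straight tube")
})

test_that("cross-sectional area is C1 at the shoulders", {
  geo <- stenosis_geometry(severity = 0.7)
  area <- function(x) pi * radius_profile(geo, x)^2
  sh <- geo$stenosis_center - geo$stenosis_length / 2
  h <- 1e-6
  dA_in <- (area(sh + h) - area(sh)) / h
  dA_out <- (area(sh) - area(sh - h)) / h
  # one-sided slopes agree to O(h * A''): the area slope itself is continuous
  expect_lt(abs(dA_in - dA_out), 10 * h * 2 * pi * geo$inlet_radius *
              geo$inlet_radius * (geo$severity / 2) * (2 * pi / geo$stenosis_length)^2)
})

test_that("body-fitted grid honors the wall and nests under refinement", {
  geo <- stenosis_geometry(severity = 0.5)
  g <- generate_grid(geo, 40, 10)
  nodes <- grid_nodes(g)
  # outermost radial node equals the local radius at every station
  expect_equal(nodes$r[, g$nr + 1], radius_profile(geo, g$xf))
  # throat radial line spans exactly half the inlet radius
  it <- which.min(abs(g$xf - geo$stenosis_center))
  expect_equal(max(nodes$r[it, ]), 0.5 * geo$inlet_radius)
  # strictly positive spacings
  expect_true(all(diff(g$xf) > 0) && all(diff(g$etaf) > 0))

  g2 <- refine_grid(g, 2L)
  expect_equal(g2$nx, 2L * g$nx)
  shared <- seq(1, g2$nx + 1, by = 2)
  expect_equal(g2$xf[shared], g$xf)
  expect_equal(g2$Rf[shared], g$Rf, tolerance = 1e-12)

  expect_error(generate_grid(geo, 6, 10), ">= 8")
  expect_error(generate_grid(stenosis_geometry(severity = 0.8), 40, 8),
               "degenerate")
})
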