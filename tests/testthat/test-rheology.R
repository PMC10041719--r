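test_that("Carreau viscosity matches the plateaus and the scalar oracle", {
  cp <- carreau_params()
  expect_identical(carreau_viscosity(0, cp), cp$eta_0)
  expect_equal(carreau_viscosity(1e12, cp), cp$eta_inf, tolerance = 1e-6)
  # independent scalar evaluation at gamma = 1/lambda: bracket is 2
  expect_equal(carreau_viscosity(1 / cp$lambda, cp),
               cp$eta_inf + (cp$eta_0 - cp$eta_inf) * 2^((cp$n - 1) / 2),
               tolerance = 1e-14)
  expect_error(carreau_viscosity(-1, cp), "nonnegative")
})

test_that("Carreau law is monotone, bounded, and collapses to Newtonian", {
  cp <- carreau_params()
  g <- 10^seq(-3, 6, length.out = 200)
  eta <- carreau_viscosity(g, cp)
  expect_true(all(diff(eta) < 0))
  expect_true(all(eta <= cp$eta_0 & eta >= cp$eta_inf))

  nw <- newtonian_params(2.7e-3)
  expect_equal(carreau_viscosity(g, nw), rep(2.7e-3, length(g)))
  expect_error(carreau_params(eta_inf = 0.06, eta_0 = 0.003), "eta_0 >= eta_inf")
})

test_that("shear-rate magnitude reproduces hand-evaluated invariants", {
  # rigid/uniform motion
  expect_identical(shear_rate_magnitude(0, 0, 0, 0, 0), 0)
  # pure axial shear du_x/dr = g -> |g|
  expect_equal(shear_rate_magnitude(0, 3.2), 3.2)
  expect_equal(shear_rate_magnitude(0, -3.2), 3.2)
  # Poiseuille wall: du_x/dr = -2U/R
  U <- 0.5; R <- 1.5e-3
  expect_equal(shear_rate_magnitude(0, -2 * U / R), 2 * U / R)
  # pure extension (incompressible axisymmetric): du_x/dx = e,
  # du_r/dr = hoop = -e/2 -> sqrt(3) e
  e <- 2.0
  expect_equal(shear_rate_magnitude(e, 0, 0, -e / 2, -e / 2), sqrt(3) * e)
})

test_that("solver shear-rate kernel agrees with the reference formula", {
  geo <- stenosis_geometry(severity = 0.6)
  sc <- scenario(0.6, geometry = geo,
                 solver = solver_config(grid_nx = 40, grid_nr = 12))
  g <- generate_grid(geo, 40, 12)
  ctx <- solver_context(sc, g)
  set.seed(7)
  f <- new_flow_field(ctx)
  f$u[] <- rnorm(length(f$u), sd = 0.1)
  f$v[] <- rnorm(length(f$v), sd = 0.01)
  f$v[, 1] <- 0; f$v[, g$nr + 1] <- 0
  gam <- stenoflow:::.sf_shear_rate(f$u, f$v, ctx$Rc, ctx$Rpc, ctx$etac,
                                    ctx$dxi, ctx$deta)
  # reference: central-difference gradients assembled in R, fed through
  # shear_rate_magnitude()
  nx <- g$nx; nr <- g$nr
  uc <- 0.5 * (f$u[1:nx, ] + f$u[2:(nx + 1), ])
  vc <- 0.5 * (f$v[, 1:nr] + f$v[, 2:(nr + 1)])
  i <- 20; j <- 6  # interior cell
  dudxi <- (f$u[i + 1, j] - f$u[i, j]) / ctx$dxi
  dudeta <- (uc[i, j + 1] - uc[i, j - 1]) / (2 * ctx$deta)
  dvdxi <- (vc[i + 1, j] - vc[i - 1, j]) / (2 * ctx$dxi)
  dvdeta <- (f$v[i, j + 1] - f$v[i, j]) / ctx$deta
  cross <- ctx$etac[j] * ctx$Rpc[i] / ctx$Rc[i]
  ref <- shear_rate_magnitude(
    dudxi - cross * dudeta, dudeta / ctx$Rc[i],
    dvdxi - cross * dvdeta, dvdeta / ctx$Rc[i],
    vc[i, j] / (ctx$etac[j] * ctx$Rc[i]))
  expect_equal(gam[i, j], ref, tolerance = 1e-12)
})
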