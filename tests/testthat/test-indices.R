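test_that("TAWSS and OSI reproduce hand-integrated signals", {
  # constant signal
  expect_equal(tawss(rep(2.5, 50)), 2.5)
  expect_equal(tawss(rep(-2.5, 50)), 2.5)
  expect_equal(osi(rep(2.5, 50)), 0)
  expect_equal(tawss(rep(0, 50)), 0)
  expect_equal(osi(rep(0, 50)), 0)  # zero-signal convention

  # +2 Pa for the first half period, -1 Pa for the second:
  # TAWSS = (2*T/2 + 1*T/2)/T = 1.5, OSI = 0.5*(1 - (T/2)/(3T/2)) = 1/3.
  # Sample points straddle the jump so the trapezoid rule is exact.
  e <- 1e-12
  times <- c(0, 0.5 - e, 0.5 + e, 1)
  w <- c(2, 2, -1, -1)
  expect_equal(tawss(w, times, 1), 1.5, tolerance = 1e-9)
  expect_equal(osi(w, times, 1), 1 / 3, tolerance = 1e-9)

  # perfect alternation: zero net integral
  expect_equal(osi(c(2, 2, -2, -2), times, 1), 0.5, tolerance = 1e-9)
})

test_that("RRT is the algebraic inverse with a documented sentinel", {
  expect_identical(rrt(1, 0), 1)
  expect_equal(rrt(1.5, 1 / 3), 2, tolerance = 1e-9)
  expect_identical(rrt(5, 0.5), 1e9)    # diverging limit capped
  expect_identical(rrt(0, 0.2), 1e9)
  expect_identical(rrt(3, 0.5, ceiling = 1e6), 1e6)
  expect_error(rrt(-1, 0.1), "nonnegative")
  expect_error(rrt(1, 0.7), "0, 0.5")
})

test_that("index algebra properties hold for randomized signals", {
  set.seed(42)
  n <- 100
  for (k in 1:200) {
    w <- runif(n, -1, 1) * 10^runif(1, -2, 2)
    o <- osi(w)
    ta <- tawss(w)
    expect_gte(o, 0); expect_lte(o, 0.5)
    expect_gte(ta, 0)
    # sign-flip invariance
    expect_equal(osi(-w), o, tolerance = 1e-12)
    expect_equal(tawss(-w), ta, tolerance = 1e-12)
    # RRT algebraic inverse wherever finite
    r <- rrt(ta, o)
    if (r < 1e9) expect_equal(r * (1 - 2 * o) * ta, 1, tolerance = 1e-9)
  }
})

test_that("2x time refinement changes TAWSS/OSI by < 1% on smooth signals", {
  T <- 0.8
  f <- function(t) 3 * sin(2 * pi * t / T) + 0.8 * cos(4 * pi * t / T) + 0.5
  for (n in c(101L)) {
    t1 <- seq(0, T, length.out = n)
    t2 <- seq(0, T, length.out = 2L * n - 1L)
    expect_equal(tawss(f(t1), t1, T), tawss(f(t2), t2, T), tolerance = 0.01)
    expect_equal(osi(f(t1), t1, T), osi(f(t2), t2, T), tolerance = 0.01)
  }
})

test_that("wall shear stress from records: sign, window and Poiseuille", {
  sc <- poiseuille_scenario(nx = 40L, nr = 16L)
  g <- generate_grid(sc$geometry, 40L, 16L)
  M <- 51
  times <- seq(0, 0.8, length.out = M)
  # synthetic parabolic near-wall profile: u_t(eta) = U (1 - eta^2)
  U <- 0.5
  deta <- g$deta
  ut1 <- matrix(U * (1 - (1 - deta / 2)^2), g$nx, M)
  ut2 <- matrix(U * (1 - (1 - 3 * deta / 2)^2), g$nx, M)
  rec <- synthetic_record(ut1, ut2, times, g, sc)
  s <- wall_shear_stress(rec, newtonian_params(3.45e-3))
  # exact for a quadratic profile: tau = mu * 2U/R
  expect_equal(as.vector(s$wss),
               rep(3.45e-3 * 2 * U / 1.5e-3, length(s$wss)),
               tolerance = 1e-10)
  # reversing the flow flips the sign everywhere
  rec2 <- synthetic_record(-ut1, -ut2, times, g, sc)
  s2 <- wall_shear_stress(rec2, newtonian_params(3.45e-3))
  expect_equal(s2$wss, -s$wss)
  # record must cover a full period
  rec3 <- synthetic_record(ut1[, 1:10], ut2[, 1:10], times[1:10], g, sc)
  expect_error(wall_shear_stress(rec3), "full period")
})

test_that("probe series: linear pressure drop and offset validation", {
  sc <- poiseuille_scenario(nx = 60L, nr = 16L)
  g <- generate_grid(sc$geometry, 60L, 16L)
  M <- 11
  times <- seq(0, 0.8, length.out = M)
  # linear axial pressure, quiescent velocity
  dp <- 100; L <- sc$geometry$vessel_length
  pin <- sc$outlet_pressure + dp
  axis_p <- matrix(pin - dp * g$xc / L, g$nx, M)
  rec <- synthetic_record(matrix(0, g$nx, M), matrix(0, g$nx, M),
                          times, g, sc, axis_p = axis_p)
  pr <- probe_series(rec, probe_offset = 3e-3)
  # linear drop between probes 6 mm apart
  expect_equal(pr$dp_anterior_posterior,
               rep(dp * 6e-3 / L, M), tolerance = 1e-9)
  expect_equal(pr$u_center, rep(0, M))
  expect_error(probe_series(rec, probe_offset = 16e-3), "outside")
})

test_that("severity summary duplicates a single case into identical rows", {
  sc <- poiseuille_scenario(nx = 40L, nr = 16L)
  g <- generate_grid(sc$geometry, 40L, 16L)
  M <- 21
  times <- seq(0, 0.8, length.out = M)
  ut1 <- matrix(rep(0.1 * sin(2 * pi * times / 0.8 + 0.3) + 0.2, each = g$nx),
                g$nx, M)
  rec <- synthetic_record(ut1, 0.5 * ut1, times, g, sc,
                          axis_p = matrix(rnorm(g$nx * M), g$nx, M),
                          axis_u = matrix(abs(rnorm(g$nx * M)), g$nx, M))
  case <- list(severity = 0.5, maps = index_maps(rec),
               probes = probe_series(rec), record = rec)
  tab <- severity_summary(list(case, case))
  expect_identical(nrow(tab), 2L)
  expect_equal(tab[1, -1], tab[2, -1], ignore_attr = TRUE)
})
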