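// Stepping kernels for the axisymmetric projection solver.
//
// Mapped coordinates: xi = x (uniform), eta = r / R(x) in [0, 1].
// Staggered (MAC) layout in the mapped rectangle:
//   u (axial velocity)   at x-faces, eta-centers: (nx+1) x nr
//   v (radial velocity)  at x-centers, eta-faces: nx x (nr+1)
//   p (pressure)         at cell centers:         nx x nr
// Chain rule: d/dx|_r = d/dxi - (eta R'/R) d/deta,  d/dr = (1/R) d/deta.
// Conservative continuity: d(eta R^2 u)/dxi + d(eta R (v - eta R' u))/deta = 0.
//
// The predictor treats eta-direction diffusion implicitly (Thomas solves per
// axial line; the near-wall spacing makes it stiff), xi-diffusion and
// advection explicitly. Viscous metric cross terms are dropped (locally
// orthogonal approximation); continuity, pressure gradients and advection
// carry the full mapped metrics.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// quadratic ghost beyond the wall enforcing zero wall velocity:
// value at eta = 1 + deta/2 from values at 1 - deta/2 and 1 - 3 deta/2
static inline double wall_ghost(double u1, double u2) {
  return -2.0 * u1 + u2 / 3.0;
}

static inline double upwind1(double vel, double fm, double f0, double fp,
                             double h) {
  return vel > 0 ? vel * (f0 - fm) / h : vel * (fp - f0) / h;
}

// fu / fv carry the explicit per-point forcing (the lagged pressure
// gradient of the incremental scheme), entering the rhs before the
// implicit radial solve so the discrete steady momentum balance is exact.
// [[Rcpp::export(name = ".sf_predict")]]
List sf_predict(NumericMatrix u, NumericMatrix v, NumericMatrix visc,
                NumericMatrix fu, NumericMatrix fv,
                NumericVector Rf, NumericVector Rpf,
                NumericVector Rc, NumericVector Rpc,
                NumericVector etac, NumericVector etaf,
                double dxi, double deta, double dt, double rho,
                int scheme) {
  const int nx = visc.nrow(), nr = visc.ncol();
  NumericMatrix us(nx + 1, nr), vs(nx, nr + 1);

  // ---------------- u predictor: interior faces fi = 1..nx-1 ----------------
  // rhs with explicit advection + xi diffusion
  NumericMatrix rhs_u(nx + 1, nr);
  for (int j = 0; j < nr; ++j) {
    const double eta = etac[j];
    for (int fi = 1; fi < nx; ++fi) {
      const double uu = u(fi, j);
      const double vbar = 0.25 * (v(fi - 1, j) + v(fi - 1, j + 1) +
                                  v(fi, j) + v(fi, j + 1));
      const double etadot = (vbar - eta * Rpf[fi] * uu) / Rf[fi];

      // xi advection
      double dadv;
      if (scheme == 2 && uu > 0 && fi >= 2) {
        dadv = uu * (3.0 * u(fi, j) - 4.0 * u(fi - 1, j) + u(fi - 2, j)) /
               (2.0 * dxi);
      } else if (scheme == 2 && uu <= 0 && fi <= nx - 2) {
        dadv = uu * (-3.0 * u(fi, j) + 4.0 * u(fi + 1, j) - u(fi + 2, j)) /
               (2.0 * dxi);
      } else {
        dadv = upwind1(uu, u(fi - 1, j), u(fi, j), u(fi + 1, j), dxi);
      }

      // eta advection (ghosts: axis mirror, wall quadratic zero)
      const double um = (j == 0) ? u(fi, 0) : u(fi, j - 1);
      const double up = (j == nr - 1)
        ? wall_ghost(u(fi, nr - 1), u(fi, nr - 2)) : u(fi, j + 1);
      double eadv;
      if (scheme == 2 && etadot > 0 && j >= 2) {
        eadv = etadot * (3.0 * u(fi, j) - 4.0 * u(fi, j - 1) + u(fi, j - 2)) /
               (2.0 * deta);
      } else if (scheme == 2 && etadot <= 0 && j <= nr - 3) {
        eadv = etadot * (-3.0 * u(fi, j) + 4.0 * u(fi, j + 1) + -u(fi, j + 2)) /
               (2.0 * deta);
      } else {
        eadv = upwind1(etadot, um, u(fi, j), up, deta);
      }

      // explicit xi diffusion: cells fi-1 (west), fi (east) flank face fi
      const double muE = visc(fi, j), muW = visc(fi - 1, j);
      const double difx = (muE * (u(fi + 1, j) - u(fi, j)) -
                           muW * (u(fi, j) - u(fi - 1, j))) / (dxi * dxi * rho);

      rhs_u(fi, j) = uu + dt * (-(dadv + eadv) + difx + fu(fi, j));
    }
  }

  // implicit eta diffusion per axial face (Thomas)
  {
    std::vector<double> a(nr), b(nr), c(nr), d(nr), cp(nr), dp(nr);
    for (int fi = 1; fi < nx; ++fi) {
      const double R2 = Rf[fi] * Rf[fi];
      for (int j = 0; j < nr; ++j) {
        // viscosity at eta-faces j and j+1 of this column (4-cell averages)
        double muS = 0, muN;
        if (j > 0) {
          muS = 0.25 * (visc(fi - 1, j - 1) + visc(fi - 1, j) +
                        visc(fi, j - 1) + visc(fi, j));
        }
        if (j < nr - 1) {
          muN = 0.25 * (visc(fi - 1, j) + visc(fi - 1, j + 1) +
                        visc(fi, j) + visc(fi, j + 1));
        } else {
          muN = 0.5 * (visc(fi - 1, nr - 1) + visc(fi, nr - 1));
        }
        const double fac = dt / (rho * etac[j] * R2 * deta * deta);
        const double cS = fac * etaf[j] * muS;     // etaf[0] = 0 kills axis flux
        const double cN = fac * etaf[j + 1] * muN;
        if (j < nr - 1) {
          a[j] = -cS;
          b[j] = 1.0 + cS + cN;
          c[j] = -cN;
        } else {
          // wall flux with quadratic zero-velocity ghost:
          // flux_N = etaf[nr] muN (ghost - u_j)/deta, ghost = -2 u_j + u_{j-1}/3
          a[j] = -cS - cN / 3.0;
          b[j] = 1.0 + cS + 3.0 * cN;
          c[j] = 0.0;
        }
        d[j] = rhs_u(fi, j);
      }
      // Thomas
      cp[0] = c[0] / b[0];
      dp[0] = d[0] / b[0];
      for (int j = 1; j < nr; ++j) {
        const double m = b[j] - a[j] * cp[j - 1];
        cp[j] = c[j] / m;
        dp[j] = (d[j] - a[j] * dp[j - 1]) / m;
      }
      us(fi, nr - 1) = dp[nr - 1];
      for (int j = nr - 2; j >= 0; --j) us(fi, j) = dp[j] - cp[j] * us(fi, j + 1);
    }
  }
  // boundary faces: zero velocity gradient plus the forcing difference
  // relative to the adjacent interior face, so the inlet/outlet Dirichlet
  // pressures drive the flow while fully developed flow stays exact
  for (int j = 0; j < nr; ++j) {
    us(0, j) = us(1, j) + dt * (fu(0, j) - fu(1, j));
    us(nx, j) = us(nx - 1, j) + dt * (fu(nx, j) - fu(nx - 1, j));
  }

  // ---------------- v predictor: interior eta-faces k = 1..nr-1 -------------
  NumericMatrix rhs_v(nx, nr + 1);
  for (int k = 1; k < nr; ++k) {
    const double ef = etaf[k];
    for (int i = 0; i < nx; ++i) {
      const double vv = v(i, k);
      const double ubar = 0.25 * (u(i, k - 1) + u(i, k) +
                                  u(i + 1, k - 1) + u(i + 1, k));
      const double etadot = (vv - ef * Rpc[i] * ubar) / Rc[i];

      // xi advection with zero-gradient ghosts
      const double vm = (i == 0) ? v(0, k) : v(i - 1, k);
      const double vp = (i == nx - 1) ? v(nx - 1, k) : v(i + 1, k);
      double dadv;
      if (scheme == 2 && ubar > 0 && i >= 2) {
        dadv = ubar * (3.0 * v(i, k) - 4.0 * v(i - 1, k) + v(i - 2, k)) /
               (2.0 * dxi);
      } else if (scheme == 2 && ubar <= 0 && i <= nx - 3) {
        dadv = ubar * (-3.0 * v(i, k) + 4.0 * v(i + 1, k) - v(i + 2, k)) /
               (2.0 * dxi);
      } else {
        dadv = upwind1(ubar, vm, vv, vp, dxi);
      }

      // eta advection (v = 0 held at axis k=0 and wall k=nr)
      double eadv;
      if (scheme == 2 && etadot > 0 && k >= 2) {
        eadv = etadot * (3.0 * v(i, k) - 4.0 * v(i, k - 1) + v(i, k - 2)) /
               (2.0 * deta);
      } else if (scheme == 2 && etadot <= 0 && k <= nr - 2) {
        eadv = etadot * (-3.0 * v(i, k) + 4.0 * v(i, k + 1) - v(i, k + 2)) /
               (2.0 * deta);
      } else {
        eadv = upwind1(etadot, v(i, k - 1), vv, v(i, k + 1), deta);
      }

      // explicit xi diffusion; viscosity at x-face/eta-face corners
      double muE, muW;
      if (i < nx - 1) {
        muE = 0.25 * (visc(i, k - 1) + visc(i, k) +
                      visc(i + 1, k - 1) + visc(i + 1, k));
      } else {
        muE = 0.5 * (visc(i, k - 1) + visc(i, k));
      }
      if (i > 0) {
        muW = 0.25 * (visc(i - 1, k - 1) + visc(i - 1, k) +
                      visc(i, k - 1) + visc(i, k));
      } else {
        muW = 0.5 * (visc(i, k - 1) + visc(i, k));
      }
      const double difx = (muE * (vp - vv) - muW * (vv - vm)) /
                          (dxi * dxi * rho);

      rhs_v(i, k) = vv + dt * (-(dadv + eadv) + difx + fv(i, k));
    }
  }

  {
    // implicit eta diffusion per axial center, rows k = 1..nr-1;
    // Dirichlet v = 0 at axis (k = 0) and wall (k = nr)
    const int m = nr - 1;
    std::vector<double> a(m), b(m), c(m), d(m), cp(m), dp(m);
    for (int i = 0; i < nx; ++i) {
      const double R2 = Rc[i] * Rc[i];
      for (int k = 1; k < nr; ++k) {
        const double ef = etaf[k];
        const double fac = dt / (rho * ef * R2 * deta * deta);
        const double cS = fac * etac[k - 1] * visc(i, k - 1);
        const double cN = fac * etac[k] * visc(i, k);
        const double mu0 = 0.5 * (visc(i, k - 1) + visc(i, k));
        const double r = ef * Rc[i];
        const double hoop = dt * mu0 / (rho * r * r); // - mu v / r^2, implicit
        const int q = k - 1;
        a[q] = -cS;
        b[q] = 1.0 + cS + cN + hoop;
        c[q] = -cN;
        d[q] = rhs_v(i, k);
      }
      cp[0] = c[0] / b[0];
      dp[0] = d[0] / b[0];
      for (int q = 1; q < m; ++q) {
        const double mm = b[q] - a[q] * cp[q - 1];
        cp[q] = c[q] / mm;
        dp[q] = (d[q] - a[q] * dp[q - 1]) / mm;
      }
      vs(i, nr - 1) = dp[m - 1];
      for (int q = m - 2; q >= 0; --q) {
        vs(i, q + 1) = dp[q] - cp[q] * vs(i, q + 2);
      }
      vs(i, 0) = 0.0;
      vs(i, nr) = 0.0;
    }
  }

  return List::create(_["u"] = us, _["v"] = vs);
}

// [[Rcpp::export(name = ".sf_divergence")]]
List sf_divergence(NumericMatrix u, NumericMatrix v,
                   NumericVector Rf, NumericVector Rpc, NumericVector Rc,
                   NumericVector etac, NumericVector etaf,
                   double dxi, double deta) {
  const int nx = v.nrow(), nr = u.ncol();
  NumericMatrix D(nx, nr);
  double scale = 0.0;
  for (int j = 0; j < nr; ++j) {
    const double eta = etac[j];
    for (int i = 0; i < nx; ++i) {
      const double FxE = eta * Rf[i + 1] * Rf[i + 1] * u(i + 1, j);
      const double FxW = eta * Rf[i] * Rf[i] * u(i, j);
      double FN = 0.0, FS = 0.0;
      if (j + 1 < nr) { // north eta-face (wall face flux is exactly zero)
        const double ef = etaf[j + 1];
        const double uc = 0.25 * (u(i, j) + u(i, j + 1) +
                                  u(i + 1, j) + u(i + 1, j + 1));
        FN = ef * Rc[i] * (v(i, j + 1) - ef * Rpc[i] * uc);
      }
      if (j > 0) {
        const double ef = etaf[j];
        const double uc = 0.25 * (u(i, j - 1) + u(i, j) +
                                  u(i + 1, j - 1) + u(i + 1, j));
        FS = ef * Rc[i] * (v(i, j) - ef * Rpc[i] * uc);
      }
      D(i, j) = (FxE - FxW) / dxi + (FN - FS) / deta;
      const double loc = (std::abs(FxE) + std::abs(FxW)) / dxi +
                         (std::abs(FN) + std::abs(FS)) / deta;
      if (loc > scale) scale = loc;
    }
  }
  return List::create(_["D"] = D, _["scale"] = scale);
}

// Applies u -= coef * Gx(phi), v -= coef * Gr(phi) in place (on copies).
// pin / pout are Dirichlet pressures on the inlet / outlet faces (length nr);
// pass zeros for correction increments.
// [[Rcpp::export(name = ".sf_correct")]]
List sf_correct(NumericMatrix u, NumericMatrix v, NumericMatrix phi,
                NumericVector pin, NumericVector pout,
                NumericVector Rf, NumericVector Rpf, NumericVector Rc,
                NumericVector etac, double dxi, double deta, double coef) {
  const int nx = phi.nrow(), nr = phi.ncol();
  NumericMatrix uc(clone(u)), vc(clone(v));
  for (int j = 0; j < nr; ++j) {
    const double eta = etac[j];
    // boundary faces: half-cell one-sided gradient to the Dirichlet value
    uc(0, j) -= coef * (phi(0, j) - pin[j]) / (0.5 * dxi);
    uc(nx, j) -= coef * (pout[j] - phi(nx - 1, j)) / (0.5 * dxi);
    for (int fi = 1; fi < nx; ++fi) {
      double g = (phi(fi, j) - phi(fi - 1, j)) / dxi;
      const double rp = Rpf[fi];
      if (rp != 0.0) {
        // deta derivative averaged over the two flanking columns
        double dW, dE;
        if (j == 0) {
          dW = (phi(fi - 1, 1) - phi(fi - 1, 0)) / deta;
          dE = (phi(fi, 1) - phi(fi, 0)) / deta;
        } else if (j == nr - 1) {
          dW = (phi(fi - 1, nr - 1) - phi(fi - 1, nr - 2)) / deta;
          dE = (phi(fi, nr - 1) - phi(fi, nr - 2)) / deta;
        } else {
          dW = (phi(fi - 1, j + 1) - phi(fi - 1, j - 1)) / (2.0 * deta);
          dE = (phi(fi, j + 1) - phi(fi, j - 1)) / (2.0 * deta);
        }
        g -= eta * rp / Rf[fi] * 0.5 * (dW + dE);
      }
      uc(fi, j) -= coef * g;
    }
  }
  for (int i = 0; i < nx; ++i) {
    for (int k = 1; k < nr; ++k) {
      vc(i, k) -= coef * (phi(i, k) - phi(i, k - 1)) / (Rc[i] * deta);
    }
  }
  return List::create(_["u"] = uc, _["v"] = vc);
}

// Cell-centered second-invariant shear rate (mapped gradients, hoop term
// included). Mirrors the R reference shear_rate_magnitude(), which tests use
// to cross-check this kernel.
// [[Rcpp::export(name = ".sf_shear_rate")]]
NumericMatrix sf_shear_rate(NumericMatrix u, NumericMatrix v,
                            NumericVector Rc, NumericVector Rpc,
                            NumericVector etac, double dxi, double deta) {
  const int nx = v.nrow(), nr = u.ncol();
  NumericMatrix g(nx, nr);
  for (int j = 0; j < nr; ++j) {
    for (int i = 0; i < nx; ++i) {
      const double uc = 0.5 * (u(i, j) + u(i + 1, j));
      const double vc = 0.5 * (v(i, j) + v(i, j + 1));
      const double dudxi = (u(i + 1, j) - u(i, j)) / dxi;
      double dudeta;
      if (j == 0) {
        const double ucp = 0.5 * (u(i, 1) + u(i + 1, 1));
        dudeta = (ucp - uc) / (2.0 * deta);
      } else if (j == nr - 1) {
        const double ucm = 0.5 * (u(i, j - 1) + u(i + 1, j - 1));
        const double ghost = wall_ghost(uc, ucm);
        dudeta = (ghost - ucm) / (2.0 * deta);
      } else {
        const double ucp = 0.5 * (u(i, j + 1) + u(i + 1, j + 1));
        const double ucm = 0.5 * (u(i, j - 1) + u(i + 1, j - 1));
        dudeta = (ucp - ucm) / (2.0 * deta);
      }
      const double dvdeta = (v(i, j + 1) - v(i, j)) / deta;
      double dvdxi;
      if (i == 0) {
        dvdxi = (0.5 * (v(1, j) + v(1, j + 1)) - vc) / dxi;
      } else if (i == nx - 1) {
        dvdxi = (vc - 0.5 * (v(i - 1, j) + v(i - 1, j + 1))) / dxi;
      } else {
        dvdxi = (0.5 * (v(i + 1, j) + v(i + 1, j + 1)) -
                 0.5 * (v(i - 1, j) + v(i - 1, j + 1))) / (2.0 * dxi);
      }
      const double cross = etac[j] * Rpc[i] / Rc[i];
      const double du_dx = dudxi - cross * dudeta;
      const double du_dr = dudeta / Rc[i];
      const double dv_dx = dvdxi - cross * dvdeta;
      const double dv_dr = dvdeta / Rc[i];
      const double hoop = vc / (etac[j] * Rc[i]);
      g(i, j) = std::sqrt(2.0 * (du_dx * du_dx + dv_dr * dv_dr + hoop * hoop) +
                          (du_dr + dv_dx) * (du_dr + dv_dx));
    }
  }
  return g;
}

// Stable time-step bound: advective CFL combined harmonically with the
// explicit axial-diffusion limit.
// [[Rcpp::export(name = ".sf_dt_limit")]]
double sf_dt_limit(NumericMatrix u, NumericMatrix v, NumericMatrix visc,
                   NumericVector Rc, NumericVector Rpc, NumericVector etac,
                   double dxi, double deta, double cfl, double rho) {
  const int nx = v.nrow(), nr = u.ncol();
  double smax = 1e-12, mumax = 0.0;
  for (int j = 0; j < nr; ++j) {
    for (int i = 0; i < nx; ++i) {
      const double uc = 0.5 * (u(i, j) + u(i + 1, j));
      const double vc = 0.5 * (v(i, j) + v(i, j + 1));
      const double etadot = (vc - etac[j] * Rpc[i] * uc) / Rc[i];
      const double s = std::abs(uc) / dxi + std::abs(etadot) / deta;
      if (s > smax) smax = s;
      if (visc(i, j) > mumax) mumax = visc(i, j);
    }
  }
  const double dt_adv = cfl / smax;
  const double dt_vx = 0.8 * dxi * dxi * rho / (2.0 * mumax);
  return 1.0 / (1.0 / dt_adv + 1.0 / dt_vx);
}
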