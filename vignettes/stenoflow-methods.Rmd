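---
title: "stenoflow: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stenoflow: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stenoflow` simulates time-resolved pulsatile blood flow through idealized
stenosed coronary vessels and post-processes the wall-shear environment
(TAWSS, OSI, RRT) and probe-point hemodynamics across a severity sweep from
30% to 80% diameter stenosis. This vignette is the package's own account of
the model, its assumptions, the numerical scheme, and the design decisions
that were genuinely open.

## The physical model

Blood is treated as an incompressible, homogeneous, shear-thinning fluid
with density $\rho = 1060$ kg/m$^3$:

$$\rho\left(\frac{\partial \mathbf u}{\partial t}
  + \mathbf u \cdot \nabla \mathbf u\right)
  = -\nabla p + \nabla\cdot\tau, \qquad \nabla\cdot\mathbf u = 0,
  \qquad \tau = 2\,\eta(\dot\gamma)\,D,$$

with the Carreau viscosity

$$\eta(\dot\gamma) = \eta_\infty + (\eta_0 - \eta_\infty)
   \left[1 + (\lambda\dot\gamma)^2\right]^{(n-1)/2},$$

using the standard whole-blood constants $\eta_\infty = 3.45\times10^{-3}$,
$\eta_0 = 5.6\times10^{-2}$ kg/(m s), $n = 0.3568$, $\lambda = 3.313$ s. The
shear rate is the second invariant $\dot\gamma = \sqrt{2\,D\!:\!D}$ of the
rate-of-deformation tensor; in the axisymmetric setting this includes the
hoop strain $u_r/r$, whose axis singularity is handled by the analytic
limit $u_r/r \to \partial u_r/\partial r$, not by clamping. Setting
$\eta_0 = \eta_\infty$ collapses the model to a Newtonian fluid; this drives
the analytic validation mode against Poiseuille flow.

The flow is solved as laminar. At the scales simulated here (diameter
$\approx 3$ mm, velocities $\lesssim 1.4$ m/s, effective kinematic
viscosity $\gtrsim 3.3\times10^{-6}$ m$^2$/s) the Reynolds number stays
below roughly 1100 -- transitional at worst -- and a two-equation
turbulence closure on a desk-scale axisymmetric grid would add model
complexity without testable fidelity. This laminar treatment is the main
fidelity gap relative to patient-scale studies that employ a shear-stress
transport closure, and it is listed under limitations below.

## Geometry and severity convention

Patient vessels are replaced by a parametric, rigid, axisymmetric conduit:
inlet radius 1.5 mm (a typical proximal LAD lumen), length 30 mm, and a
cosine-shaped constriction of length 10 mm centered at 15 mm,

$$R(x) = R_0\left[1 - \frac{s}{2}
  \left(1 + \cos\frac{2\pi(x - x_c)}{\ell}\right)\right],$$

whose cross-sectional area is $C^1$ at the shoulders. **Severity $s$ is
fractional diameter reduction** -- an "80% stenosis" leaves 20% of the
reference diameter -- which is the common angiographic convention; an
area-based convention would shift every severity-dependent result, so the
choice is recorded here and in the configuration. Severities of 0.95 and
above are refused because the grid degenerates at the throat. Eccentric
plaques, branch vessels, curvature and wall compliance are out of scope.

## Boundary conditions and the synthetic waveform

The inlet carries a time-varying pressure $P_a(t)$ emulating a clinically
measured proximal (FFR-wire) trace; the outlet carries the constant mean
distal pressure. For the six bank severities the outlet values are the
printed clinical ones -- 8843, 8041, 7819, 7446, 7377 and 7229 Pa for 30%
through 80% -- and the walls are rigid with no slip; the axis carries the
usual symmetry conditions.

The measured waveform's numerical trace is not published, so the waveforms
module synthesizes a smooth periodic stand-in with the features that are
documented: a biphasic shape with systolic peak at $t = 0.4$ s, built from
a raised-cosine systolic bump (width $T/2$) plus a smaller dicrotic wave,
on a period $T = 0.8$ s (75 bpm, placing peak systole mid-cycle). The
closed form guarantees two contracts exactly: the time average equals the
configured mean and the maximum (mean + pulse amplitude) occurs at the peak
time. The default mean of 9300 Pa makes the outlet-to-inlet mean ratios
span 0.95 to 0.78 across the bank -- a realistic FFR range. The generator is
deterministic; there is no randomness anywhere in the solver or the
scenario bank.

### Calibrating the inlet drive

Applying the full clinical pressure difference to the idealized conduit
would overdrive it: a patient's mean gradient is dissipated along a
branched, curved, diffusely diseased tree, whereas the idealized vessel
concentrates all resistance in one smooth constriction. The package
therefore anchors each bank scenario to a *printed hemodynamic outcome* by
scaling the whole inlet excess over the outlet pressure (mean drive and
pulse together) with a single factor $\beta$, found by a safeguarded
secant/bisection iteration with closed-loop re-simulation
(`calibrate_inlet_waveform()`, 2% relative tolerance):

| severity | anchored outcome | target |
|---|---|---|
| 30% | peak throat axis velocity | 0.12 m/s |
| 40--60% | peak throat axis velocity | 0.45 m/s |
| 70% | peak anterior--posterior probe $\Delta P$ | 750 Pa |
| 80% | peak anterior--posterior probe $\Delta P$ | 1000 Pa |

An amplitude-only calibration mode (`mode = "amplitude"`) is also provided;
it preserves the mean drive and is the right tool when the mean gradient is
trusted. For the severe bank cases it cannot reach the printed
$\Delta P$ targets -- the mean drive alone already produces a larger
transstenotic difference, so the response has a floor above the target --
and it fails with diagnostics rather than silently mis-calibrating. That
floor is why the bank uses the drive-scaling mode.

The stored bank scales ($\beta$ = 0.0156, 0.0421, 0.0388, 0.0354, 0.2076,
0.2689 for 30% through 80%) were computed once with the calibration
routine on a 120 x 24 grid over 2 cycles and are kept as defaults so that
default sweeps skip the calibration loop; `calibrate_inlet_waveform()`
reproduces them from scratch.

Probe pressures are reported **relative to the scenario outlet pressure**:
the clinical traces mix absolute and gauge conventions, and differences
relative to the outlet are the quantity the probe analyses actually use.
Probes sit on the axis at the throat and one inlet diameter (3 mm)
upstream/downstream of it; the offset is configurable since the original
probe coordinates are not documented.

## Numerical scheme

The solver is a Chorin-style projection method on a body-fitted structured
grid in mapped coordinates $\xi = x$, $\eta = r/R(x)$, with a staggered
(MAC) arrangement in the mapped rectangle: axial velocity on axial faces,
radial velocity on radial faces, pressure in cell centers.

* **Advection** is explicit and upwind-biased: second-order upwind by
  default (`upwind2`), with a first-order fallback adjacent to boundaries
  and a pure first-order scheme (`upwind1`) available. The full mapped
  metric terms are retained in the advective derivatives.
* **Diffusion** splits by direction: radial diffusion is implicit (Thomas
  solves per axial line; the near-wall radial spacing makes it stiff, and
  the Carreau low-shear plateau raises the viscosity by a factor of 16
  exactly where the shear vanishes), axial diffusion is explicit. The
  viscous *metric cross terms* are dropped (a locally orthogonal
  approximation with $O(R'^2)$ local error near the stenosis shoulders,
  where $|R'| \le 0.38$ at 80% severity); continuity, pressure gradients
  and advection keep the full metrics. Viscosity is evaluated per cell per
  step from the previous velocity field (Picard lag); an optional
  inner-iteration mode exists and the difference between modes is
  measured in the tests.
* **Projection** is *incremental*: the lagged pressure gradient (with the
  new-time inlet pressure as boundary data) enters the predictor before
  the implicit radial solve, and the Poisson stage corrects with pressure
  increments only. A pressure-free predictor would leave an $O(\Delta t)$
  numerical slip layer at the wall -- invisible in centerline velocity or
  flux, but amplified by the one-sided wall-shear derivative into a
  percent-level WSS bias; with the incremental form the discrete steady
  momentum balance (and hence Poiseuille wall shear) is exact.
  Discrete continuity uses the conservative mapped form
  $\partial_\xi(\eta R^2 u) + \partial_\eta(\eta R (v - \eta R' u)) = 0$,
  which makes cross-sectional volume flux telescoping -- mass conservation
  between any two cross-sections holds to the projection tolerance by
  construction. The pressure solve applies the instantaneous inlet
  pressure $P_a(t+\Delta t)$ and the constant outlet pressure as Dirichlet
  data on half-cell ties and iterates a deferred correction: a separable
  five-point operator is factorized once (sparse Cholesky) and re-applied,
  while the full mapped gradient (including the $\eta R'/R$ cross term)
  enters through the velocity correction. The iteration stops when the
  scaled continuity residual falls below the configured tolerance, default
  $10^{-4}$, the convergence criterion used for the reference runs; on
  straight-tube sections the first iterate is already exact.
* **Wall and axis.** No slip enters the radial diffusion operator through
  a quadratic ghost (exact for parabolic profiles, so Poiseuille wall
  shear is reproduced without first-order wall bias); the axis uses
  symmetry mirrors, and the $\eta = 0$ metric factor annihilates axis
  fluxes naturally.
* **Time stepping.** First-order in time from rest, with the step chosen
  each step as the harmonic combination of the advective CFL bound
  (default Courant number 0.35, inside the explicit stability region of
  the second-order upwind scheme) and the explicit axial-diffusion limit,
  capped by the configured $\Delta t = 2.5\times10^{-4}$ s. Runs cover 3
  cycles by default with the first 2 discarded; the throat-pressure drift
  between the last two cycles is reported and warned about above 5%.
  Spin-up is fast here (Womersley number $\approx 0.6$): in practice the
  second cycle already repeats to a few parts in $10^9$.

Determinism is exact: identical scenarios and configurations produce
bitwise-identical records, and the acceptance checks rely on it.

### Wall shear and indices

The wall shear stress is the tangential viscous traction
$\tau_w = \eta(\dot\gamma_w)\,\partial u_t/\partial n$ evaluated with a
second-order one-sided normal derivative of the wall-tangential velocity,
with the viscosity taken as the Carreau value at the wall shear rate (the
natural reading when a constant $\mu$ appears in a wall-shear formula next
to a shear-dependent $\eta$). In the axisymmetric setting the WSS "vector"
reduces to a signed scalar (positive = downstream); both the instantaneous
signed WSS and its cycle statistics are exposed, since wall maps "at peak
systole" and time-averaged maps answer different questions:

$$\mathrm{TAWSS} = \frac1T\int_0^T |\tau_w|\,dt, \qquad
  \mathrm{OSI} = \frac12\left[1 -
  \frac{|\int_0^T \tau_w\,dt|}{\int_0^T|\tau_w|\,dt}\right], \qquad
  \mathrm{RRT} = \left[(1 - 2\,\mathrm{OSI})\,\mathrm{TAWSS}\right]^{-1}.$$

Integrals use the trapezoid rule on the recorded cadence (default 1/100 of
the period; halving the cadence moves TAWSS/OSI by well under 1% on smooth
signals). Conventions: stations with identically zero shear get OSI = 0
(not the 0/0 limit 0.5, which would paint quiescent regions as maximally
oscillatory); RRT is reported in Pa$^{-1}$ and capped at a documented
sentinel ($10^9$ Pa$^{-1}$) as OSI $\to 0.5$, where it diverges in
principle. Published RRT peaks on the $10^7$ scale are not unit-reconcilable
with Pa$^{-1}$ values and are treated as a different normalization; the
package reports its own consistent values and makes only rank-based
(co-location) claims about RRT.

## Grid-refinement study

`grid_independence_study()` reruns a scenario on a nested ladder (default
three levels, factor 2) and tabulates the **outlet velocity at a steady
solve under the peak-systole inlet pressure**, identifying the first level
where successive change drops to 2% -- the usual mesh-independence
criterion. A steady metric was chosen over full cyclic runs deliberately:
it is deterministic, it is the quantity mesh-independence statements are
made about, and it keeps the ladder's finest level affordable; the
convergence it certifies carries over to the transient scheme, which uses
the same spatial operators.

Two reductions of "outlet velocity" are tabulated. The *bulk* velocity
(volumetric flux over outlet area) is the resistance-controlled quantity
and converges cleanly (on the 80% case: 1.1% then 0.1% across a
120 x 24 / 240 x 48 / 480 x 96 ladder). The *pointwise profile maximum*
is reported alongside but is deliberately not the default convergence
metric: at high severity the outlet sits in the decaying post-stenotic
jet, whose centerline peak keeps sharpening with resolution long after
the flow rate, pressure drop and throat velocity have converged -- a
shear-layer-resolution yardstick rather than a solution-convergence one.

## Problem sizes

The package's reference grid is 240 x 48 cells (axial x radial) with 3
cycles. The test suite and the acceptance script run reduced study sizes,
chosen as the coarsest settings at which each check is meaningful: straight
tube validation on 240 x 48 (steady) and 96 x 24; pulsatile severity
sweeps on 120 x 24 with 2 cycles; the calibrated 80% study on 160 x 32
with 3 cycles after calibrating on 120 x 24; and refinement ladders from
120 x 24 (script) or 100 x 20 (tests). The 120 x 24 pulsatile solutions
sit within a few percent of the reference grid for the probe quantities
they are used for, which is well inside the tolerances of the checks that
consume them.

## What the synthetic scenarios do and do not show

The scenario bank emulates: the pressure-driven, biphasic pulsatile regime;
the printed outlet pressures; the severity ladder; and shear-thinning
rheology. Passing checks on it demonstrates that the discretization solves
the stated equations (Poiseuille/mass-conservation oracles), that the
index algebra is exact, and that the *qualitative* severity trends --
monotone transstenotic $\Delta P$ and throat velocity, the sharp 60% to
70% TAWSS rise, growing oscillatory-shear exposure, OSI/RRT co-location
away from the throat -- emerge from the physics rather than from fitting.
It does **not** show patient-level quantitative fidelity: real LAD
geometries are branched, curved and eccentric; real flow may transition to
turbulence beyond 70% severity; walls move; and the measured waveform is
richer than the two-bump stand-in. Peak wall-map magnitudes on patient
geometries (tens of Pa) are therefore not reproduced at desk scale, and
the package makes no claim that they are.

## Known limitations

* Laminar-only momentum transport (no turbulence closure).
* Axisymmetric geometry: no branches, curvature, eccentricity or
  fluid-structure interaction.
* First-order temporal accuracy; viscous metric cross terms dropped near
  steep shoulders.
* Pressure-outlet boundary: no lumped-parameter (Windkessel) coupling, so
  downstream impedance effects fold into the calibrated drive scale.
* RRT magnitudes are internally consistent (Pa$^{-1}$) but not comparable
  across publications that use other normalizations.
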