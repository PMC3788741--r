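---
title: "Methods: boundary-integral simulation of platelet-thrombus-RBC hydrodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: boundary-integral simulation of platelet-thrombus-RBC hydrodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The physical model

`thromboflow` simulates cellular blood flow in a streamwise-periodic
cylindrical arteriole (radius $R = 7.5\,\mu m$, period $L = 45\,\mu m$)
containing a mural thrombus, deformable red blood cells, and a rigid
spheroidal platelet.  At these scales the Reynolds number is
$\mathrm{Re} = \rho U D/\mu \approx 5.6\times10^{-3}$, so inertia is
neglected and the flow obeys the Stokes equations.  All coupling is
quasi-static: at each instant the velocity field is determined by the
current geometry and the elastic state of the membranes.

Units are micrometers, seconds, and mPa·s throughout.  In this system
membrane tension carries units of mPa·µm ($10^{-9}$ N/m) and bending
modulus mPa·µm³ ($10^{-21}$ J).

## Thrombus geometry

The thrombus is a smooth bump protruding from the $+y$ side of the wall,
with protrusion height

$$\eta(x, z) = h\,\exp\!\big(-\kappa\,[(z - z_c)^2/a + x^2/b]\big),
\qquad \kappa = 1.9 .$$

This canonical Gaussian form has elliptical level sets in the $x$–$z$
plane, a Gaussian $x$–$y$ profile, and apex height exactly $h$ — the three
properties the geometry is required to satisfy.  A verbatim
power-law variant $\eta = H - w^{\kappa u}$ is retained behind
`mode = "literal"` for experimentation; it is internally inconsistent
(its apex height is $H - 1$ regardless of $w$) and is not used by any
default workflow.  On the wall the lateral coordinate is taken as
circumferential arc length $R\varphi$, which keeps the displaced surface
smooth all the way around the vessel and makes the back side
($\varphi = \pi$) exactly unperturbed.

Percent area stenosis is the blocked fraction of the cross-section at the
throat, $100\int (R\eta - \eta^2/2)\,d\varphi / (\pi R^2)$, evaluated by
adaptive quadrature.  Because a Gaussian has unbounded support, the
"projection ellipse" used to normalize trajectory statistics is defined by
the 1 %-of-apex-height contour, with semi-axes
$\sqrt{\ln(100)\,a/\kappa}$ and $\sqrt{\ln(100)\,b/\kappa}$.

With the reference parameters $a = 7.5$, $b = 6$, $h = 1.2$ the canonical
bump blocks about 2 % of the throat area.  No reading of the printed
shape formula that we tried reproduces the published stenosis percentages
for these parameters, so stated stenosis values are treated as labels of
the published figures rather than as quantitative targets; all stenosis
values reported by this package are computed from the geometry.

## Hydrodynamics: periodic boundary-integral formulation

The velocity anywhere in the fluid is represented by single-layer
potentials over all immersed surfaces,

$$u(x) = U_0\,\hat z + \sum_S \int_S G^{per}(x - y)\, q_S(y)\, dS(y),$$

where $G^{per}$ is the triply periodic Stokeslet (box
$20 \times 20 \times 45\,\mu m$; the lateral period is harmless because
the no-slip vessel wall screens lateral images) and $U_0$ is the unknown
mean-flow constant of the $k = 0$ mode.  Densities are unknown on the
wall (no-slip) and on the platelet (rigid-body motion with unknown
$(U, \Omega)$, closed by zero net force and torque, plus a rank-one
regularization that removes the normal-density null space of the
single-layer operator).  RBC membranes enter as known force densities —
their elastic tractions — because the interior viscosity is treated as
matched in the flow solve (see "Viscosity contrast" below).  The flow is
driven by prescribing the volumetric flow rate $Q = U_{mean}\pi R^2$
(the physiological datum is the mean velocity, not the pressure drop);
the associated mean pressure gradient is recovered from the net
streamwise force on the wall.

The periodic Green's function uses the classical Ewald (Hasimoto) split
into a screened real-space sum and a Fourier sum.  Solver-side pair
evaluations use the identity $G^{per}(r) = \chi(|r_{mi}|)\,G^{free}(r_{mi})
+ T(r)$: the free-space part is evaluated analytically near contact
(where accuracy matters most) and blended out smoothly before the
minimum-image cut planes, while the smooth periodic remainder $T$ is
precomputed on a regular grid (Fourier part synthesized exactly by FFT)
and interpolated with periodic tricubics.  The tabulated path agrees
with the direct Ewald sum to better than $10^{-6}$ at short range and a
few $10^{-4}$ in the far field, and the direct sum itself is verified to
be independent of the splitting parameter to $10^{-8}$.

Quadrature is lumped (vertex weights) plus accurate corrections for
singular and near-singular pairs: when the target is a vertex of the
source triangle the $1/r$ kernel is integrated in polar (Duffy)
coordinates; when it is merely close, the triangle is subdivided
adaptively.  Near-wall field evaluations (the 0.5 µm probe curves) use
the same correction machinery.

The dense wall self-interaction operator is assembled and LU-factorized
once per geometry.  Cell-free tube problems then solve by block
elimination; coupled wall-platelet problems use GMRES with a
block-diagonal preconditioner (exact wall and platelet-saddle factors),
which converges in a handful of iterations because the blocks are
strongly diagonally dominant at gated separations.

Verification anchors: Poiseuille flow in the clean tube (relative $L_2$
error below 2 % at the default 24 x 48 wall mesh, flow-rate conservation
across planes to $10^{-5}$), the dilute simple-cubic sphere-array drag
(within 0.5 % of the closed form $1/(1 - 1.7601\varphi^{1/3} + \varphi -
1.5593\varphi^2)$ at $\varphi = 10^{-3}$), and the Jeffery rotation
period of an $r_e = 4$ spheroid in simple shear (within 1.5 % of
$2\pi(r_e + 1/r_e)/\dot\gamma$ at the 512-face platelet mesh).

## RBC membranes

Each membrane is a closed surface whose three Cartesian coordinate
fields are expanded in real, fully normalized spherical harmonics
(no Condon-Shortley phase) up to degree $p$ on a Gauss-Legendre x
uniform-longitude grid of $(p{+}1)(2p{+}2)$ nodes.  The forward
transform is quadrature-exact for band-limited fields; all surface
derivatives (metric, curvatures) are analytic in the basis.  Surface
divergences are evaluated through the Cartesian embedding
($\nabla_\Gamma\!\cdot v = \sum_a e_a\!\cdot\!\nabla_\Gamma v_a$), which
only ever transforms smooth Cartesian component fields and therefore
avoids the pole singularities of covariant components.

In-plane elasticity follows the Skalak-type strain-energy law with
principal tensions

$$\tau_i = \frac{G_s}{\lambda_1\lambda_2}\Big[\lambda_i^2(\lambda_i^2-1)
  + C\,\lambda_1^2\lambda_2^2(\lambda_1^2\lambda_2^2 - 1)\Big],$$

which resists areal dilatation $C$-fold more strongly than shear.
Bending is Helfrich at zero spontaneous curvature, with normal traction
$k_b[\Delta_s(2H) + 2H(2H^2 - 2K)]$; the sign convention is fixed by
requiring that bending-driven relaxation decreases the Helfrich energy
(verified against the discrete energy gradient).  Every nonlinear
product is evaluated on a 3/2-dealiased grid and truncated back to
degree $p$, which stabilizes the spectral dynamics without adding
dissipation.

The reference state is the stress-free Evans-Fung biconcave discocyte
with $R_0 = 3.91\,\mu m$ (volume $\approx 94\,\mu m^3$, area
$\approx 135\,\mu m^2$); its parameterization is a degree-5 trigonometric
polynomial and hence exactly band-limited.  Default moduli are standard
literature values for the cited constitutive family, exposed in the
configuration: $G_s = 4.2\,\mu N/m$, $C = 100$, $k_b = 2\times10^{-19}$ J.
The exact values used in the original tool chain are not published, so
all RBC-shape comparisons in the tests are property-based (cap-shape
development, conservation, fluctuation structure) rather than pointwise.

### Viscosity contrast

The cytosol/plasma viscosity ratio $\lambda$ (default 5) is carried in
the configuration and recorded with every cell, but the hydrodynamic
solve treats the interior as viscosity-matched: supporting
$\lambda \neq 1$ requires the periodic double-layer (stresslet) kernel,
which is outside this package's desk-scale scope.  The matched-viscosity
model retains the elastic membrane — the dominant source of the
cellular-flow phenomenology reproduced here (profile blunting,
fluctuations, platelet margination pressure) — but understates interior
dissipation, so cell shape relaxation is somewhat faster than with
contrast.  One measurable consequence at the desk-scale test window: the
peak near-wall speed *rises* (by roughly 10-14 %, depending on the
window length) when cells are added at
fixed flow rate — core blockage steepens the near-wall profile, and the
interior-dissipation mechanism that would slow the flow past the apex is
absent — whereas the full-scale contrast model reports a comparable
decrease.  The corresponding acceptance check is asserted in the
published direction and therefore fails under the desk-scale conditions;
the measured value is logged by the test.  This is a stated limitation,
not a tunable.

## Rigid platelet

The platelet is an oblate spheroid with semi-axes
$1.0 \times 1.0 \times 0.25\,\mu m$ (the 2 µm, aspect-ratio-0.25 shape
of the platelet-adhesion-dynamics line of work), discretized by a
recursively subdivided octasphere (512 collocation faces by default)
whose quadrature weights use curved (midpoint-lifted) triangle areas.
Pose is a unit quaternion advanced by the exponential map; the
orientation statistic $\theta_x$ is the angle between the minor axis and
$+y$ measured about $x$, wrapped to $(-\pi/2, \pi/2]$ by spheroid
symmetry.  A flipping event is a wrap crossing of $\theta_x$.

## Time stepping and gating

Each step: elastic tractions → Stokes solve → advect membrane nodes with
the local fluid velocity → advance the platelet pose → reproject
(de-alias) the membrane coefficients → volume renormalization capped at
0.1 % linear scale per step.  Time integration is explicit first order
by default, with the step chosen so no node moves more than `max_disp`
(default 0.05 µm); a `heun` option re-solves at the predicted pose and
averages the rigid-body velocities, which we use for trajectory studies
where fore-aft symmetry of the numerical orbit matters.  Membrane
stiffness (the $C G_s$ area-penalty) caps the stable step near
$\mu h_{grid}/(G_s(1+C)) \sim 4\times10^{-6}$ s at $p = 6$, which is why
cellular runs are orders of magnitude more expensive than cell-free ones.

Surfaces are kept at least `gate` (default 0.05 µm) apart: a violated
tentative step halves `dt` and retries.  Because an attracting cell can
approach the gate asymptotically, a short-range exclusion layer acts
within twice the gate — offending membrane nodes are pushed back along
the wall-inward (or cell-cell center) direction by the overlap amount.
Gate plus exclusion stand in for the unmodeled lubrication and adhesion
physics at sub-100 nm separations.

Platelet release height: the printed release prescription for the
platelet ("half of 22.5 minus h") is dimensionally inconsistent with a
15 µm vessel; we read it as the mid-gap of the constricted section,
$y = -h/2$ in centered coordinates, i.e. halfway between the thrombus
apex and the opposite wall — `release_height_midgap()`.

## Metrics

* **DPV** — maximum $v_z$ over a lumen sampling grid (default
  $64\times64\times96$, excluding a 0.1 µm boundary shell) divided by the
  non-stenotic maximum.
* **Near-wall profiles** — speeds sampled along curves at constant
  0.5 µm normal offset from the (thrombus-modified) wall;
  the wall shear estimate is $\tau = \mu v/\Delta y$.  The printed form
  of this estimate ("$\mu v \Delta y$") is dimensionally inconsistent;
  $\mu v/\Delta y$ is the only reading with stress units and matches the
  finite-offset gradient estimate.
* **Trajectory density** — the three-step procedure (project to $x$–$z$;
  count/spread per station; renormalize to 1), stations expressed in
  relative $z$ scaled by the projection-ellipse major axis.
* **Reversibility** — $\Delta\%(Z) = 100\,|x(z_c{+}Z) - x(z_c{-}Z)| /
  \max(|x(z_c{-}Z)|, 0.1\,x_{span})$; the denominator guard keeps the
  percentage meaningful for trajectories released near $x = 0$.
* **Deposition map** — per-wall-vertex minimum platelet-surface distance
  over time and releases, with the 260 nm
  $\alpha_{IIb}\beta_3$–vWF–$\alpha_{IIb}\beta_3$ bond length as the
  reactive threshold.
* **Conversions** — diameter-to-area stenosis
  $100 \cdot 0.63\,(d/100)^{1.5}$ with both constants exposed (the
  composition order of the published conversion is not stated; this
  composition is the package's choice), and in vivo DPV $v/75$ cm/s.

Platelet counts are truncated, not rounded: `floor(conc * V)` whole
platelets fit the simulation volume, which reproduces the published
"1–3 platelets" band for 150,000–450,000 µL$^{-1}$ in the thrombus-free
lumen volume (rounding would give 1–4).

## Synthetic fixtures

The generator produces (i) seeded non-overlapping initial cell
configurations (placement samples with a 0.3 µm margin above the 0.2 µm
separation requirement so dynamics start clear of the contact gate);
(ii) analytic toy cases with attached expectations (Poiseuille tube,
sphere array, spheroid in shear); and (iii) synthetic trajectory bundles
— streamlines of an incompressible channel-with-bump model flow,
$x(z) = x_0\,[1 - g\,e^{-\kappa(z-z_c)^2/a}]$, with optional smoothed
lateral noise and a known density peak at $z_c$.  The bundles emulate
the convergence/divergence structure of observed platelet paths but not
imaging noise, frame-rate effects, or out-of-plane motion; tests that
pass on them validate the metrics pipeline, not the biology.

## Problem sizes used by the tests and acceptance script

Test-suite solves use a 24 x 48 wall mesh (20 x 40 for sweep studies and
16 x 32 for cellular demonstrations), the 512-face platelet, $p = 6$
cells, and transits of 5–25 µm; the acceptance reversibility run uses a
32 x 64 wall mesh and a 25 µm transit.  These sizes are chosen so that
each study resolves the quantity it asserts (mesh-convergence checks are
part of the suite) while a full run of the suite stays desk-scale.  The
published claims about cellular effects (≈15 % near-wall velocity
reduction at Hct 10 %, fluctuations reaching 10 % of the mean, up to
10 % trajectory irreversibility) emerge at resolutions and run lengths
beyond desk scale; the scaled cellular tests here assert the direction
and existence of each effect and log the measured magnitude, and the
full-scale configuration remains available through the config interface.

## Serialization

Meshes and fields export as legacy-ASCII VTK, trajectories as CSV with a
fixed documented header, metrics as JSON, and spherical-harmonic
coefficient sets as plain CSV (degree, order, three coefficient
columns) — a deliberately dependency-free text format.

## Known limitations

* Matched interior viscosity (no double-layer); see above.
* No platelet deformability, adhesion kinetics, thrombus growth, or
  Brownian motion; the deposition map is a purely hydrodynamic proxy.
* Direct $O(N^2)$ Ewald sums bound the tractable surface counts; the
  mathematics matches the accelerated original, the complexity does not.
* First-order membrane time stepping; stiff area penalties make long
  cellular runs expensive.
* The near-wall exclusion layer is a model, not resolved lubrication.
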