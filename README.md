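# thromboflow

Boundary-integral simulation and analysis of platelet–thrombus–red-blood-cell
hydrodynamic interactions in a small arteriole.

## The problem

In arterioles of ~15 µm diameter, a growing mural thrombus changes the local
flow in ways that feed back on its own growth: near-wall velocity and shear
reorganize around the bump, red blood cells (RBCs) blunt and destabilize the
profile, and free-flowing platelets are steered toward (or away from) the
thrombus surface, where adhesion receptors can engage only within ~260 nm.
`thromboflow` is a desk-scale research code for studying exactly this
configuration: a streamwise-periodic cylindrical vessel (radius R = 7.5 µm,
period L = 45 µm) with a parametric thrombus bump, deformable spectral RBC
capsules, and a rigid spheroidal platelet, all coupled through inertialess
(Stokes, Re ≈ 5.6×10⁻³) hydrodynamics.

It is aimed at researchers in computational hemodynamics who want a compact,
fully scriptable implementation of this model class in R, with every analysis
statistic of the stenotic-flow problem built in.

## The model in brief

* **Flow**: triply periodic boundary-integral Stokes formulation.  The
  velocity is a sum of single-layer potentials of the Ewald-split periodic
  Stokeslet over wall, platelet, and membrane surfaces, plus an unknown
  mean-flow constant closed by the prescribed flow rate
  Q = U_mean · πR² (U_mean = 1128 µm/s).
* **Thrombus**: protrusion η(x,z) = h·exp(−κ[(z−z_c)²/a + x²/b]) on the +y
  wall (κ = 1.9); percent area stenosis is the blocked throat fraction.
* **RBCs**: spherical-harmonic surfaces with Skalak-type in-plane elasticity
  (shear modulus G_s, area-dilatation ratio C ≫ 1) and Helfrich bending
  (modulus k_b), advanced quasi-statically with 3/2-rule de-aliasing.
* **Platelet**: rigid 2 × 2 × 0.5 µm oblate spheroid, force- and torque-free,
  quaternion pose; its wrapped orientation angle θ_x ∈ (−π/2, π/2] defines
  flipping events.
* **Metrics**: dimensionless peak velocity (DPV) versus % area stenosis,
  near-wall velocity/shear profiles at 0.5 µm offset, platelet trajectory
  density and fore-aft reversibility, deposition-potential maps against the
  260 nm reactive threshold, flipping statistics, velocity-fluctuation
  measures, and the diameter→area stenosis conversion used for clinical
  comparisons.

Validation anchors built into the test suite: Poiseuille flow in the clean
tube, the dilute periodic sphere-array drag closed form, and the Jeffery
rotation period of a spheroid in shear.

See the methods vignette (`vignettes/thromboflow-methods.Rmd`) for the
formulation, numerical choices, and limitations.

## Worked example

A cell-free stenotic solve with the reference thrombus, plus the two
headline statistics:

```r
library(thromboflow)

vessel <- vessel_geometry()                  # R = 7.5 um, L = 45 um
shape  <- thrombus_shape(a = 7.5, b = 6, h = 1.2)
fluid  <- fluid_properties()                 # mu = 1.2 mPa s, U = 1128 um/s
params <- ewald_params()

area_stenosis(shape, vessel)
#> [1] 2.017869

wall  <- build_wall_mesh(vessel, shape, n_theta = 24, n_z = 48)
cache <- stokes_cache(wall, fluid, params)
sol   <- assemble_and_solve(wall, fluid = fluid, params = params,
                            drive = list(type = "flow_rate", U_mean = 1128),
                            cache = cache)

## near-wall speeds 0.5 um off the wall, on the thrombus centerline and on
## the opposite side of the vessel
curves <- probe_curves(vessel, shape, offset = 0.5, azimuths = c(0, pi))
prof   <- near_wall_profile(sol, curves)
round(range(prof[[1]]$speed), 1)   # thrombus side: stagnation dips + apex rise
#> [1] 218.5 631.0
round(range(prof[[2]]$speed), 1)   # back side: nearly undisturbed
#> [1] 269.9 275.8

## centerline peak velocity (Poiseuille gives 2 x 1128 = 2256 um/s)
velocity_at(matrix(c(0, 0, 7), 1, 3), sol)[3]
#> [1] 2285.394
```

The thrombus-side profile drops below its far-field value just upstream and
downstream of the bump (stagnation zones) and rises steeply over the apex,
while the back-side profile barely changes — the azimuthal asymmetry that
concentrates shear-gradient exposure on the thrombus side.  The wall shear
stress estimate at any probe point is `shear_estimate(v, 0.5, fluid$mu)`.

Cellular runs and platelet transits are driven the same way through
`simulation_config()` / `run_simulation()`, and the command-line interface
(`inst/cli/thromboflow.R`) exposes `simulate`, `sweep-stenosis`,
`sweep-release`, `metrics`, and `fixtures` subcommands over the same
functions.

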