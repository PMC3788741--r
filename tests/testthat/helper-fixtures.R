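# Shared fixtures, built lazily and memoised so expensive solves are done
# once per test run.

.fix <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fix[[key]])) .fix[[key]] <- builder()
  .fix[[key]]
}

default_vessel <- function() vessel_geometry()

## sphere coordinates sampled on the order-p SH grid
sphere_grid_surface <- function(r, p) {
  B <- thromboflow:::sh_basis_matrices(p, p)
  th <- acos(thromboflow:::gauss_legendre(p + 1)$x)
  ph <- 2 * pi * (seq_len(B$nph) - 1) / B$nph
  TH <- as.vector(outer(th, rep(1, B$nph)))
  PH <- as.vector(outer(rep(1, B$nth), ph))
  X <- cbind(r * sin(TH) * cos(PH), r * sin(TH) * sin(PH), r * cos(TH))
  sh_surface(sh_analyze(X, p), p)
}

## cell-free tube solution on a modest mesh, reused by several tests
tube_solution <- function() {
  memo("tube", function() {
    vessel <- default_vessel()
    wall <- build_wall_mesh(vessel, thrombus_shape(7.5, 6, 0), 24, 48)
    fluid <- fluid_properties()
    params <- ewald_params()
    cache <- stokes_cache(wall, fluid, params)
    assemble_and_solve(wall, fluid = fluid, params = params,
                       drive = list(type = "flow_rate", U_mean = 1128),
                       cache = cache)
  })
}

## developed cellular window: 8 cells at Hct = 10% in the stenosed tube,
## advanced 40 stabilized steps; shared by the cellular acceptance checks
cellular_window <- function() {
  memo("cellular", function() {
    shape <- thrombus_shape(7.5, 6, 1.2)
    cfg <- simulation_config(shape = shape, n_theta = 16, n_z = 32,
                             hct = 0.10, rbc_p = 6, dt_cap = 3e-6,
                             max_disp = 0.05, seed = 0)
    st <- sim_init(cfg)
    ref_sol <- assemble_and_solve(st$wall, fluid = cfg$fluid,
                                  params = cfg$ewald,
                                  drive = list(type = "flow_rate",
                                               U_mean = 1128),
                                  cache = st$cache)
    probe_pt <- matrix(c(0, 7.5 - 1.2 - 1.0, 22.5), 1)
    series <- numeric(0)
    for (k in 1:24) {
      st <- sim_step(st)
      if (k %% 2 == 0)
        series <- c(series, velocity_at(probe_pt, st$solution)[3])
    }
    list(state = st, ref_sol = ref_sol, series = series, shape = shape,
         config = cfg)
  })
}

## stenosed cell-free solution (h = 1.2 reference shape)
stenosed_solution <- function() {
  memo("stenosed", function() {
    vessel <- default_vessel()
    shape <- thrombus_shape(7.5, 6, 1.2)
    wall <- build_wall_mesh(vessel, shape, 24, 48)
    fluid <- fluid_properties()
    params <- ewald_params()
    cache <- stokes_cache(wall, fluid, params)
    sol <- assemble_and_solve(wall, fluid = fluid, params = params,
                              drive = list(type = "flow_rate",
                                           U_mean = 1128), cache = cache)
    list(sol = sol, shape = shape, vessel = vessel)
  })
}
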