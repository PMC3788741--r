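test_that("cell-free tube flow reproduces Poiseuille", {
  sol <- tube_solution()
  rr <- seq(0, 6.8, length.out = 14)
  pts <- cbind(rr * cos(0.7), rr * sin(0.7), 13.1)
  u <- velocity_at(pts, sol)
  ua <- 2 * 1128 * (1 - rr^2 / 7.5^2)
  expect_lt(sqrt(mean((u[, 3] - ua)^2)) / sqrt(mean(ua^2)), 0.02)
  # centerline peak is twice the mean
  uc <- velocity_at(matrix(c(0, 0, 7), 1, 3), sol)
  expect_equal(uc[3], 2256, tolerance = 0.02 * 2256)
  # transverse velocities vanish up to discretization error
  expect_lt(max(abs(u[, 1:2])), 0.02 * 2256)
})

test_that("flow rate is conserved across five z-planes", {
  sol <- tube_solution()
  Q <- 1128 * pi * 7.5^2
  fr <- sapply(c(0, 5, 10, 35, 40), function(z) flow_rate_at(sol, z))
  expect_true(all(abs(fr - Q) / Q < 0.005))
})

test_that("stenotic cell-free flow is mirror-symmetric in x", {
  st <- stenosed_solution()
  pts_p <- cbind(1.5, c(-2, 0, 2), 22.5)
  pts_m <- cbind(-1.5, c(-2, 0, 2), 22.5)
  up <- velocity_at(pts_p, st$sol)
  um <- velocity_at(pts_m, st$sol)
  expect_lt(max(abs(up[, 2:3] - um[, 2:3])), 1e-4 * 2256)
  expect_lt(max(abs(up[, 1] + um[, 1])), 1e-4 * 2256)
})

test_that("thrombus disturbance is localized (small one period upstream)", {
  st <- stenosed_solution()
  ref <- tube_solution()
  pts <- cbind(c(0, 1, -2, 0), c(0, 2, 1, -3), 5)
  du <- velocity_at(pts, st$sol) - velocity_at(pts, ref)
  expect_lt(max(sqrt(rowSums(du^2))), 0.03 * 1128)
})

test_that("a freely suspended platelet in the tube is force- and torque-free", {
  vessel <- vessel_geometry()
  wall <- build_wall_mesh(vessel, thrombus_shape(7.5, 6, 0), 20, 40)
  fluid <- fluid_properties()
  params <- ewald_params()
  cache <- stokes_cache(wall, fluid, params)
  pl <- rigid_platelet(center = c(1, -2, 10))
  sol <- assemble_and_solve(wall, platelets = list(pl), fluid = fluid,
                            params = params,
                            drive = list(type = "flow_rate", U_mean = 1128),
                            cache = cache)
  p <- sol$platelets[[1]]
  qm <- matrix(p$q, ncol = 3, byrow = TRUE)
  Fnet <- colSums(qm * p$surf$w)
  rc <- sweep(p$surf$pts, 2, pl$center)
  Tnet <- colSums(cbind(rc[, 2] * qm[, 3] - rc[, 3] * qm[, 2],
                        rc[, 3] * qm[, 1] - rc[, 1] * qm[, 3],
                        rc[, 1] * qm[, 2] - rc[, 2] * qm[, 1]) * p$surf$w)
  scale <- fluid$mu * 1128 * 1.0          # mu U a
  expect_lt(max(abs(Fnet)) / scale, 1e-5)
  expect_lt(max(abs(Tnet)) / scale, 1e-5)
  # it advects downstream at a plausible mid-stream speed
  expect_gt(p$U[3], 1128)
  expect_lt(p$U[3], 2256)
  # separation gate refuses overlapping configurations
  too_close <- rigid_platelet(center = c(0, -7.3, 10))
  expect_error(assemble_and_solve(wall, platelets = list(too_close),
                                  fluid = fluid, params = params,
                                  drive = list(type = "flow_rate",
                                               U_mean = 1128),
                                  cache = cache), "separation gate")
})

test_that("sphere-array drag matches the dilute closed form", {
  ratio <- sphere_array_drag_ratio(phi = 1e-3, subdiv = 3)
  expect_lt(abs(ratio - hashimoto_drag_ratio(1e-3)) /
              hashimoto_drag_ratio(1e-3), 0.01)
})

test_that("spheroid rotation in shear follows the Jeffery period", {
  Tsim <- jeffery_period(r_e = 4, gamma = 1, subdiv = 3, n_angles = 12)
  Tj <- 2 * pi * (4 + 1 / 4)
  expect_lt(abs(Tsim - Tj) / Tj, 0.03)
})
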