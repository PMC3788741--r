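test_that("a symmetric-plane release stays on the symmetry plane", {
  shape <- thrombus_shape(7.5, 6, 1.2)
  cfg <- simulation_config(shape = shape, n_theta = 20, n_z = 40,
                           platelet_release = list(
                             x = 0, y = release_height_midgap(shape),
                             z = 18),
                           max_disp = 0.3, travel_target = 6)
  tr <- run_simulation(cfg)
  expect_gt(nrow(tr), 5)
  expect_lt(max(abs(tr$x)), 1e-3)
})

test_that("identical config and seed give identical trajectories", {
  shape <- thrombus_shape(7.5, 6, 0)
  cfg <- simulation_config(shape = shape, n_theta = 16, n_z = 32,
                           platelet_release = list(x = 1, y = -2, z = 5),
                           max_disp = 0.3, travel_target = 3, seed = 11)
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$z, t2$z)
  expect_identical(t1$theta_x, t2$theta_x)
})

test_that("trajectory bookkeeping: monotone time, unwrapped z, pose columns", {
  shape <- thrombus_shape(7.5, 6, 0)
  cfg <- simulation_config(shape = shape, n_theta = 16, n_z = 32,
                           platelet_release = list(x = 0.5, y = -1, z = 43),
                           max_disp = 0.3, travel_target = 5)
  tr <- run_simulation(cfg)
  expect_true(all(diff(tr$t) > 0))
  # crossed the periodic seam: unwrapped z keeps increasing
  expect_true(all(diff(tr$z) > 0))
  expect_gt(max(tr$z), 45)
  expect_true(all(abs(tr$qw^2 + tr$qx^2 + tr$qy^2 + tr$qz^2 - 1) < 1e-9))
  expect_true(all(is.finite(tr$d_wall)))
})

test_that("an Hct > 0 run carries the full cell count and fluctuates", {
  cfg <- simulation_config(shape = thrombus_shape(7.5, 6, 0),
                           n_theta = 16, n_z = 32, hct = 0.10, rbc_p = 6,
                           dt_cap = 3e-6, seed = 0)
  st <- sim_init(cfg)
  expect_length(st$rbcs, 8)
  st1 <- sim_step(st)
  expect_length(st1$cell_velocity, 8)
  # deterministic placement
  st2 <- sim_init(cfg)
  expect_equal(st$rbcs[[3]]$current$coef, st2$rbcs[[3]]$current$coef)
  # membranes advect with finite velocity and the state stays gated
  expect_true(all(sapply(st1$cell_velocity, function(u) all(is.finite(u)))))
  expect_gte(min(unlist(st1$separations)), cfg$gate)
})

test_that("time stepping converges first order for the rigid transit", {
  shape <- thrombus_shape(7.5, 6, 1.2)
  xs <- sapply(c(0.6, 0.3, 0.15), function(md) {
    cfg <- simulation_config(shape = shape, n_theta = 16, n_z = 32,
                             platelet_release = list(x = 1, y = -0.6,
                                                     z = 19),
                             max_disp = md, travel_target = 4.5)
    tr <- run_simulation(cfg)
    approx(tr$z, tr$x, xout = 23, ties = "ordered")$y
  })
  e1 <- abs(xs[1] - xs[3]); e2 <- abs(xs[2] - xs[3])
  # halving the step shrinks the Richardson difference
  expect_lt(e2, 0.75 * e1)
})

test_that("stationarity check behaves on canonical series", {
  expect_true(stationarity_check(rep(1.5, 20)))
  expect_false(stationarity_check(1:20))
})
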