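test_that("hematocrit arithmetic reproduces the cell count", {
  expect_equal(rbc_count_for_hct(0.10), 8L)
  expect_equal(rbc_count_for_hct(1e-4), 0L)
  # doubling the period doubles the count before rounding
  v2 <- vessel_geometry(L = 90)
  expect_equal(0.10 * pi * 7.5^2 * 90 / 94,
               2 * (0.10 * pi * 7.5^2 * 45 / 94), tolerance = 1e-12)
  expect_equal(rbc_count_for_hct(0.10, v2), 17L)  # round(16.9)
})

test_that("platelet count range truncates whole platelets", {
  vol <- lumen_fluid_volume(vessel_geometry(), thrombus_shape(7.5, 6, 1.2))
  expect_equal(platelet_count_range(150000, 450000, vol * 1e-9), c(1L, 3L))
  expect_equal(platelet_count_range(0, 450000, vol * 1e-9)[1], 0L)
  # volume doubling doubles counts before truncation
  expect_equal(platelet_count_range(150000, 450000, 2 * vol * 1e-9),
               c(2L, 7L))
})

test_that("RBC placement is seeded, feasible, and respects separations", {
  vessel <- vessel_geometry()
  shape <- thrombus_shape(7.5, 6, 1.2)
  poses <- place_rbcs(8, vessel, shape, seed = 0)
  expect_length(poses, 8)
  poses2 <- place_rbcs(8, vessel, shape, seed = 0)
  expect_equal(poses, poses2)
  # verify pairwise and wall separations on the realized surfaces
  ref <- biconcave_reference(8)
  nodes <- lapply(poses, function(ps)
    sweep(sh_synthesize(ref$coef, 8) %*% t(ps$rotation), 2, ps$center, "+"))
  wall <- build_wall_mesh(vessel, shape, 32, 64)
  for (nd in nodes) {
    dw <- thromboflow:::point_mesh_distance_cpp(
      cbind(nd[, 1], nd[, 2], nd[, 3] %% 45), wall$vertices,
      wall$triangles, 45)
    expect_gt(min(dw), 0.2 - 0.05)  # mesh-chord tolerance below clearance
  }
  for (i in 1:7) for (j in (i + 1):8) {
    dmin <- Inf
    for (s in c(-45, 0, 45)) {
      ni <- nodes[[i]]; ni[, 3] <- ni[, 3] + s
      d2 <- outer(rowSums(ni^2), rowSums(nodes[[j]]^2), "+") -
        2 * ni %*% t(nodes[[j]])
      dmin <- min(dmin, sqrt(max(min(d2), 0)))
    }
    expect_gt(dmin, 0.2)
  }
  # single cell sits inside the lumen
  p1 <- place_rbcs(1, vessel, NULL, seed = 1)
  expect_lt(sqrt(sum(p1[[1]]$center[1:2]^2)), 7.5)
})

test_that("synthetic bundles encode their ground truth", {
  shape <- thrombus_shape(7.5, 6, 1.2)
  b0 <- synthetic_trajectory_bundle(shape, n = 12, noise_sd = 0, seed = 4)
  td0 <- trajectory_density(b0, shape)
  expect_equal(td0$rel_z[which.max(td0$density)], 0, tolerance = 0.05)
  # same seed reproduces; different seed with noise differs
  b1 <- synthetic_trajectory_bundle(shape, n = 12, noise_sd = 0.1, seed = 4)
  b2 <- synthetic_trajectory_bundle(shape, n = 12, noise_sd = 0.1, seed = 4)
  expect_equal(b1[[3]]$x, b2[[3]]$x)
  # law of large numbers: noisy density approaches the noise-free curve
  bn <- synthetic_trajectory_bundle(shape, n = 100, noise_sd = 0.05,
                                    seed = 4)
  tdn <- trajectory_density(bn, shape)
  keep <- !is.na(tdn$density) & !is.na(td0$density)
  expect_lt(max(abs(tdn$density[keep] - td0$density[keep])), 0.05)
})

test_that("toy cases carry their analytic expectations", {
  tc <- toy_case("sphere_array", phi = 1e-3)
  expect_equal(tc$expectation$value, hashimoto_drag_ratio(1e-3))
  expect_equal(tc$a, (1e-3 * 20^3 * 3 / (4 * pi))^(1 / 3))
  tj <- toy_case("spheroid_shear", r_e = 4)
  expect_equal(tj$expectation$value, 2 * pi * 4.25)
  tt <- toy_case("cell_free_tube")
  expect_s3_class(tt$config, "simulation_config")
  expect_equal(tt$expectation$peak, 2256)
  expect_error(toy_case("unknown_case"))
})
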