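test_that("trajectory density follows the three-step procedure", {
  shape <- thrombus_shape(7.5, 6, 1.2)
  # two parallel straight trajectories: constant density 1
  trs <- lapply(1:2, function(i) as_trajectory(data.frame(
    t = seq(0, 1, length.out = 40), x = i, y = 0,
    z = seq(0, 45, length.out = 40))))
  td <- trajectory_density(trs, shape)
  expect_true(all(td$density[!is.na(td$density)] == 1))
  # synthetic converging bundle peaks at the designed station
  bundle <- synthetic_trajectory_bundle(shape, n = 24, noise_sd = 0,
                                        seed = 3)
  td2 <- trajectory_density(bundle, shape)
  expect_lt(abs(td2$rel_z[which.max(td2$density)]), 0.5)
  expect_equal(max(td2$density, na.rm = TRUE), 1)
  # permutation invariance
  td3 <- trajectory_density(rev(bundle), shape)
  expect_equal(td2$density, td3$density)
  # y-fluctuation exclusion removes flagged tracks; all-excluded errors
  with_exc <- synthetic_trajectory_bundle(shape, n = 5, seed = 3,
                                          include_excluded = TRUE)
  td4 <- trajectory_density(with_exc, shape)
  expect_equal(attr(td4, "excluded"), 2)
  only_exc <- with_exc[6:7]
  expect_error(trajectory_density(c(only_exc, only_exc[1]), shape),
               "fewer than 2")
})

test_that("reversibility metric recovers constructed asymmetries", {
  shape <- thrombus_shape(7.5, 6, 1.2)
  bundle <- synthetic_trajectory_bundle(shape, n = 8, noise_sd = 0, seed = 1)
  # noise-free symmetric bundle: zero mismatch
  rv <- reversibility(bundle[[4]], 22.5, seq(0.5, 4, by = 0.5))
  expect_lt(max(rv$delta_pct), 1e-9)
  # inserted 5% downstream offset is recovered
  tr <- bundle[[8]]
  xx <- tr$x
  up <- approx(tr$z, tr$x, xout = 22.5 - (tr$z[tr$z > 22.5] - 22.5),
               ties = "ordered")$y
  xx[tr$z > 22.5] <- up * 1.05
  tr2 <- as_trajectory(data.frame(t = tr$t, x = xx, y = tr$y, z = tr$z))
  rv2 <- reversibility(tr2, 22.5, c(1, 2, 3))
  expect_equal(rv2$delta_pct, rep(5, 3), tolerance = 0.1)
  # non-monotone z is flagged and still computed on the first crossing
  trz <- as_trajectory(data.frame(t = 1:5, x = c(0, 1, 1, 1, 2),
                                  y = 0, z = c(10, 21, 23, 22, 35)))
  rvz <- reversibility(trz, 22.5, c(1))
  expect_true(attr(rvz, "recirculation"))
})

test_that("deposition maps compose by element-wise minimum", {
  vessel <- vessel_geometry()
  wall <- build_wall_mesh(vessel, thrombus_shape(7.5, 6, 1.2), 16, 32)
  mk <- function(y) as_trajectory(data.frame(
    t = seq(0, 1, length.out = 5), x = 0, y = y,
    z = seq(5, 40, length.out = 5), qw = 1, qx = 0, qy = 0, qz = 0))
  r1 <- mk(-3); r2 <- mk(-4.5)
  m1 <- deposition_map(list(r1), wall)
  m2 <- deposition_map(list(r2), wall)
  m12 <- deposition_map(list(r1, r2), wall)
  expect_equal(m12$min_dist, pmin(m1$min_dist, m2$min_dist),
               tolerance = 1e-12)
  expect_equal(m12$global_min, min(m1$global_min, m2$global_min))
  # glued far from the wall: distances near the constant gap
  far <- as_trajectory(data.frame(t = c(0, 1), x = 0, y = 0, z = c(22, 22.6),
                                  qw = 1, qx = 0, qy = 0, qz = 0))
  mf <- deposition_map(list(far), wall)
  expect_gt(min(mf$min_dist), 7.5 - 1.2 - 1 - 0.3)
  # brute-force oracle on a coarse case
  pl <- rigid_platelet(center = c(0, -3, 22))
  pm <- spheroid_surface(pl)
  d_brute <- thromboflow:::point_mesh_distance_cpp(
    wall$vertices, pm$vertices, pm$triangles, -1)
  one <- as_trajectory(data.frame(t = 0:1, x = 0, y = -3, z = c(22, 22.0001),
                                  qw = 1, qx = 0, qy = 0, qz = 0))
  mo <- deposition_map(list(one), wall)
  expect_lt(max(abs(pmin(d_brute, mo$min_dist) - mo$min_dist)), 1e-3)
})

test_that("flipping events are located from wrap crossings", {
  z <- seq(0, 110, by = 0.25)
  th <- ((z / 22) * pi) %% pi
  th[th > pi / 2] <- th[th > pi / 2] - pi
  fe <- flipping_events(th, z)
  expect_equal(unique(round(fe$distances, 9)), 22)
  # constant angle: no events
  fe0 <- flipping_events(rep(0.3, 100), seq_len(100))
  expect_equal(length(fe0$event_z), 0)
})

test_that("fluctuation and conversion operations follow their formulas", {
  expect_equal(fluctuation_stats(rep(3, 10)), 0)
  s <- c(10, 11, 9, 10)
  expect_equal(fluctuation_stats(s), 100 * 1 / 10)
  expect_equal(stenosis_convert(100), 63)
  expect_equal(stenosis_convert(50, power = 1.5, factor = 0.63),
               100 * 0.63 * 0.5^1.5)
  expect_equal(dpv_invivo(150), 2)
  expect_equal(dpv_invivo(75), 1)
})

test_that("stationarity check distinguishes ramps from stationary series", {
  expect_true(stationarity_check(rep(5, 40)))
  expect_false(stationarity_check(seq(1, 10, length.out = 40)))
  # AR(1) probe-velocity surrogate: stationary only after burn-in
  set.seed(2)
  n <- 600
  x <- numeric(n); x[1] <- 30        # far from the stationary mean 10
  for (i in 2:n) x[i] <- 10 + 0.5 * (x[i - 1] - 10) + rnorm(1, sd = 0.5)
  expect_false(stationarity_check(x[1:40], window = 20))
  expect_true(stationarity_check(x[(n - 299):n], window = 150))
})
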