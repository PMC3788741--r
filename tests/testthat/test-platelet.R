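test_that("collocation surface matches closed-form spheroid areas", {
  pl <- rigid_platelet()                       # 1.0 x 1.0 x 0.25, 512 faces
  m <- spheroid_surface(pl)
  expect_equal(nrow(m$triangles), 512)
  expect_lt(abs(mesh_area(m) - oblate_area(1, 0.25)) / oblate_area(1, 0.25),
            0.005)
  ps <- rigid_platelet(1, 1)
  expect_lt(abs(mesh_area(spheroid_surface(ps)) - 4 * pi) / (4 * pi), 0.005)
  # rotation is rigid: pairwise distances preserved
  pl2 <- rigid_platelet(quaternion = quat_from_rotvec(c(0.3, -1.1, 0.7)))
  d1 <- dist(spheroid_surface(pl)$vertices[1:50, ])
  d2 <- dist(spheroid_surface(pl2)$vertices[1:50, ])
  expect_lt(max(abs(d1 - d2)), 1e-12)
})

test_that("pose updates follow the quaternion exponential map", {
  pl <- rigid_platelet()
  # pure translation
  a <- update_pose(pl, c(1, 2, 3), c(0, 0, 0), 0.5)
  expect_equal(a$center, c(0.5, 1, 1.5))
  expect_equal(a$quaternion, pl$quaternion)
  # full turn returns the orientation (up to quaternion sign)
  b <- update_pose(pl, c(0, 0, 0), c(2 * pi / 0.1, 0, 0), 0.1)
  expect_lt(min(sum((b$quaternion - pl$quaternion)^2),
                sum((b$quaternion + pl$quaternion)^2)), 1e-20)
  # two half steps equal one full step for constant (U, Omega)
  set.seed(4)
  U <- rnorm(3); Om <- rnorm(3)
  h2 <- update_pose(update_pose(pl, U, Om, 0.05), U, Om, 0.05)
  h1 <- update_pose(pl, U, Om, 0.1)
  expect_lt(max(abs(h2$quaternion - h1$quaternion)), 1e-10)
  expect_lt(max(abs(h2$center - h1$center)), 1e-10)
  # unit norm maintained
  expect_lt(abs(sqrt(sum(h2$quaternion^2)) - 1), 1e-10)
})

test_that("orientation angle wraps on (-pi/2, pi/2] with the flat state at 0", {
  expect_equal(orientation_angle_x(rigid_platelet()), 0)
  perp <- rigid_platelet(quaternion = quat_from_rotvec(c(pi / 2, 0, 0)))
  expect_equal(orientation_angle_x(perp), pi / 2)
  over <- rigid_platelet(quaternion = quat_from_rotvec(c(pi / 2 + 0.05, 0, 0)))
  expect_equal(orientation_angle_x(over), -pi / 2 + 0.05, tolerance = 1e-10)
  # quaternion path agrees with a rotation-matrix oracle for random poses
  set.seed(5)
  for (k in 1:20) {
    q <- thromboflow:::quat_normalize(rnorm(4))
    pl <- rigid_platelet(quaternion = q)
    Rm <- quat_to_matrix(q) %*%
      matrix(c(1, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3, byrow = TRUE)
    minor <- Rm %*% c(0, 0, 1)
    ang <- atan2(minor[3], minor[2]) %% pi
    if (ang > pi / 2 + 1e-9) ang <- ang - pi
    expect_equal(orientation_angle_x(pl), ang, tolerance = 1e-10)
  }
})
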