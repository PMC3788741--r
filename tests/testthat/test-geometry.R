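test_that("bump height has the canonical Gaussian form", {
  shape <- thrombus_shape(a = 7.5, b = 6, h = 1.2)
  # apex value is exactly h
  expect_equal(bump_height(0, 22.5, shape), 1.2)
  # direct arithmetic oracle at an off-apex point
  expect_equal(bump_height(1, 23.5, shape),
               1.2 * exp(-1.9 * (1^2 / 7.5 + 1^2 / 6)))
  # Gaussian decay beyond the far contour
  zfar <- 22.5 + sqrt(14 * 7.5 / 1.9) + 0.01
  expect_lt(bump_height(0, zfar, shape), 1e-6 * 1.2)
  # symmetry in x and in (z - z_c); periodic in z
  expect_equal(bump_height(0.7, 21, shape), bump_height(-0.7, 24, shape))
  expect_equal(bump_height(0.3, 21 + 45, shape), bump_height(0.3, 21, shape))
})

test_that("literal printed bump form is available behind a flag", {
  lit <- thrombus_shape(7.5, 6, h = 1.2, mode = "literal", H = 2.2, w = 2)
  expect_equal(bump_height(0, 22.5, lit), 2.2 - 1)   # apex H - w^0
  expect_true(all(bump_height(c(5, 10), 22.5, lit) >= 0))
})

test_that("wall mesh converges to the cylinder and is consistently oriented", {
  vessel <- vessel_geometry()
  flat <- thrombus_shape(7.5, 6, 0)
  m <- build_wall_mesh(vessel, flat, 64, 128)
  expect_lt(abs(mesh_area(m) - 2 * pi * 7.5 * 45) / (2 * pi * 7.5 * 45),
            0.005)
  # refinement halves the area defect roughly 4x (second order)
  m1 <- build_wall_mesh(vessel, flat, 24, 48)
  m2 <- build_wall_mesh(vessel, flat, 48, 96)
  e1 <- abs(mesh_area(m1) - 2 * pi * 7.5 * 45)
  e2 <- abs(mesh_area(m2) - 2 * pi * 7.5 * 45)
  expect_lt(e2 / e1, 0.35)
  # bumped mesh: normals point into the lumen, refinement changes area little
  shape <- thrombus_shape(7.5, 6, 1.2)
  mb <- build_wall_mesh(vessel, shape, 32, 64)
  inward <- -cbind(mb$centroids[, 1], mb$centroids[, 2], 0)
  expect_true(all(rowSums(mb$normals * inward) > 0))
  mb2 <- build_wall_mesh(vessel, shape, 64, 128)
  expect_lt(abs(mesh_area(mb2) - mesh_area(mb)) / mesh_area(mb2), 0.002)
  expect_true(any(mb$tags == "thrombus"))
})

test_that("area stenosis matches a rasterization oracle and is monotone", {
  vessel <- vessel_geometry()
  expect_equal(area_stenosis(thrombus_shape(7.5, 6, 0), vessel), 0)
  shape <- thrombus_shape(7.5, 6, h = 7.5)
  S <- area_stenosis(shape, vessel)
  # pixel-rasterization oracle on a 2000^2 grid at the throat plane
  n <- 2000
  xs <- seq(-7.5, 7.5, length.out = n)
  g <- expand.grid(x = xs, y = xs)
  inside_circle <- g$x^2 + g$y^2 < 7.5^2
  phi <- atan2(g$x, g$y)
  r <- sqrt(g$x^2 + g$y^2)
  eta <- thromboflow:::bump_height_azimuthal(phi, 22.5, shape, vessel)
  blocked <- inside_circle & (r > 7.5 - eta)
  S_raster <- 100 * sum(blocked) / sum(inside_circle)
  expect_lt(abs(S - S_raster), 0.05)
  # monotone in h
  Ss <- sapply(c(1, 2, 3, 5), function(h)
    area_stenosis(thrombus_shape(7.5, 6, h), vessel))
  expect_true(all(diff(Ss) > 0))
})

test_that("probe curves keep constant wall distance and the back side is flat", {
  vessel <- vessel_geometry()
  flat <- thrombus_shape(7.5, 6, 0)
  cv <- probe_curves(vessel, flat, 0.5, azimuths = 0, n = 32)[[1]]
  expect_equal(max(abs(cv$points[, 2] - 7)), 0, tolerance = 1e-9)
  expect_equal(max(abs(cv$points[, 1])), 0, tolerance = 1e-9)
  shape <- thrombus_shape(7.5, 6, 1.2)
  cvb <- probe_curves(vessel, shape, 0.5, azimuths = c(0, pi), n = 64)[[1]]
  # point-to-mesh distance oracle over the apex
  wall <- build_wall_mesh(vessel, shape, 64, 128)
  d <- thromboflow:::point_mesh_distance_cpp(cvb$points, wall$vertices,
                                             wall$triangles, vessel$L)
  apex <- abs(cvb$z - 22.5) < 3
  expect_lt(max(abs(d[apex] - 0.5)) / 0.5, 0.01)
  # azimuth-pi curve unaffected by the bump
  cvpi <- probe_curves(vessel, shape, 0.5, azimuths = pi, n = 64)[[1]]
  expect_lt(max(abs(cvpi$points[, 2] + 7)), 1e-6)
  # offset larger than the local gap is refused
  expect_error(probe_curves(vessel, thrombus_shape(7.5, 6, 7.4), 0.5,
                            azimuths = 0, n = 128), "gap")
})

test_that("lumen volume and projection ellipse follow the shape parameters", {
  vessel <- vessel_geometry()
  expect_equal(lumen_fluid_volume(vessel, NULL), pi * 7.5^2 * 45)
  shape <- thrombus_shape(7.5, 6, 1.2)
  v <- lumen_fluid_volume(vessel, shape)
  expect_lt(v, pi * 7.5^2 * 45)
  expect_equal(projection_major_axis(shape),
               2 * sqrt(log(100) * 7.5 / 1.9))
})
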