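test_that("biconcave reference has the classic discocyte measures", {
  ref <- biconcave_reference(16)
  m <- membrane_measures(ref)
  expect_lt(abs(m$volume - 94) / 94, 0.03)
  expect_lt(abs(m$area - 135) / 135, 0.03)
  # symmetry under z -> -z and rotation about z: mirroring the grid values
  # reproduces the surface
  nodes <- sh_synthesize(ref$coef, ref$p)
  flipped <- cbind(nodes[, 1], nodes[, 2], -nodes[, 3])
  cf_f <- sh_analyze(flipped, ref$p)
  s_f <- sh_surface(cf_f, ref$p)
  g1 <- surface_geometry(ref); g2 <- surface_geometry(s_f)
  expect_lt(abs(g1$volume - g2$volume), 1e-8)
  expect_lt(abs(g1$area - g2$area), 1e-8)
  # axisymmetry: x/y coefficient energy is confined to |m| = 1 modes
  expect_lt(max(abs(ref$coef[c(1, 3), 1:2])), 1e-10)
})

test_that("in-plane traction vanishes in the reference state", {
  ref <- biconcave_reference(12)
  mod <- membrane_moduli(kb_J = 0)
  et <- elastic_traction(rbc_state(ref, ref, mod))
  expect_lt(max(abs(et$traction)) / mod$Gs, 1e-10)
})

test_that("equibiaxial sphere inflation matches the closed-form tension", {
  p <- 12
  lam <- 1.04
  mod <- membrane_moduli(kb_J = 0)
  st <- rbc_state(sphere_grid_surface(2 * lam, p), sphere_grid_surface(2, p),
                  mod)
  et <- elastic_traction(st)
  tau <- mod$Gs * ((lam^2 - 1) + mod$C * lam^2 * (lam^4 - 1))
  expect_lt(max(abs(et$tension_iso - tau)) / tau, 1e-6)
  # traction magnitude is the Laplace load 2 tau / r, directed inward
  tn <- sqrt(rowSums(et$traction^2))
  expect_lt(max(abs(tn - 2 * tau / (2 * lam))) / (2 * tau / (2 * lam)),
            1e-6)
  g <- surface_geometry(st$current)
  expect_lt(max(rowSums(et$traction * g$normal)), 0)
})

test_that("a sphere is bending-stationary and tractions self-equilibrate", {
  p <- 12
  mod <- membrane_moduli(Gs_uN_m = 1e-9, kb_J = 2e-19)
  et <- elastic_traction(rbc_state(sphere_grid_surface(2, p),
                                   sphere_grid_surface(2, p), mod))
  expect_lt(max(abs(et$traction)) / mod$kb, 1e-8)
  # self-equilibrium of a deformed state: zero net force and torque
  set.seed(3)
  ref <- biconcave_reference(p)
  cf <- ref$coef
  deg <- rep(0:p, times = 2 * (0:p) + 1)
  pick <- deg >= 1 & deg <= 4
  cf[pick, ] <- cf[pick, ] + 0.05 * rnorm(sum(pick) * 3)
  st <- rbc_state(sh_surface(cf, p), ref)
  et <- elastic_traction(st)
  g <- surface_geometry(st$current)
  scale <- sum(sqrt(rowSums(et$traction^2)) * g$dA)
  Fnet <- colSums(et$traction * g$dA)
  Tnet <- colSums(cbind(
    g$nodes[, 2] * et$traction[, 3] - g$nodes[, 3] * et$traction[, 2],
    g$nodes[, 3] * et$traction[, 1] - g$nodes[, 1] * et$traction[, 3],
    g$nodes[, 1] * et$traction[, 2] - g$nodes[, 2] * et$traction[, 1]) *
      g$dA)
  # quadrature accuracy of the truncated traction field
  expect_lt(max(abs(Fnet)) / scale, 1e-4)
  expect_lt(max(abs(Tnet)) / (scale * 4), 1e-4)
})

test_that("mesh inversion (degenerate metric) is detected", {
  p <- 8
  ref <- sphere_grid_surface(1, p)
  cf <- ref$coef
  cf[, 3] <- 0                       # collapse onto the z = 0 plane
  bad <- sh_surface(cf, p)
  expect_error(suppressWarnings(elastic_traction(rbc_state(bad, ref))),
               "stretch|metric")
})

test_that("volume renormalization is capped and converges to the target", {
  p <- 8
  s <- sphere_grid_surface(1.1, p)
  v0 <- membrane_measures(s)$volume
  s1 <- thromboflow:::rbc_renormalize(s, target_volume = v0 * 0.9)
  v1 <- membrane_measures(s1)$volume
  # one call moves at most 0.3% in volume (0.1% linear cap)
  expect_lt(abs(v1 / v0 - 1), 0.0031)
  for (k in 1:40) s1 <- thromboflow:::rbc_renormalize(s1, v0 * 0.99)
  expect_equal(membrane_measures(s1)$volume, v0 * 0.99, tolerance = 1e-6)
})
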