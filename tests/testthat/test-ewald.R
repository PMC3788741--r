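test_that("periodic Stokeslet is independent of the splitting parameter", {
  p1 <- ewald_params(box = c(45, 45, 45), xi = 1, tol = 1e-12)
  p2 <- ewald_params(box = c(45, 45, 45), xi = 2, tol = 1e-12)
  r <- c(1, 2, 3)
  G1 <- ewald_stokeslet(r, p1)
  G2 <- ewald_stokeslet(r, p2)
  expect_lt(max(abs(G1 - G2)) / max(abs(G1)), 1e-8)
  expect_equal(G1, t(G1), tolerance = 1e-12)
})

test_that("large boxes approach the free-space Oseen tensor", {
  r <- c(0.3, 0.6, 0.9)
  pbig <- ewald_params(box = rep(450, 3), xi = 0.15, tol = 1e-8)
  Gb <- ewald_stokeslet(r, pbig)
  Go <- oseen_tensor(r)
  expect_lt(max(abs(Gb - Go)) / max(abs(Go)), 0.01)
})

test_that("far field decays as 1/r", {
  pbig <- ewald_params(box = rep(900, 3), xi = 0.12, tol = 1e-8)
  rs <- seq(2, 8, length.out = 8)
  mag <- sapply(rs, function(rr)
    norm(ewald_stokeslet(rr * c(1, 1, 1) / sqrt(3), pbig), "F"))
  slope <- unname(coef(lm(log(mag) ~ log(rs)))[2])
  expect_lt(abs(slope + 1), 0.02)
})

test_that("singular separations are refused", {
  p <- ewald_params(box = c(20, 20, 20))
  expect_error(ewald_stokeslet(c(0, 0, 0), p), "lattice")
  expect_error(ewald_stokeslet(c(20, 0, 0), p), "lattice")
})

test_that("tabulated kernel path reproduces the direct Ewald sum", {
  pp <- ewald_params(box = c(20, 20, 45), xi = 1, tol = 1e-10)
  tab <- thromboflow:::ewald_table(pp)
  set.seed(6)
  worst_far <- 0; worst_near <- 0
  for (k in 1:25) {
    r <- runif(3, -10, 10) * c(1, 1, 2.2)
    Gd <- thromboflow:::ewald_stokeslet_cpp(r, pp$box, pp$xi, pp$tol)
    Gt <- thromboflow:::periodic_kernel_tab(r, tab, mu = 1 / (8 * pi))
    worst_far <- max(worst_far, max(abs(Gt - Gd)) / max(abs(Gd)))
  }
  for (k in 1:25) {
    r <- runif(3, -1, 1)
    Gd <- thromboflow:::ewald_stokeslet_cpp(r, pp$box, pp$xi, pp$tol)
    Gt <- thromboflow:::periodic_kernel_tab(r, tab, mu = 1 / (8 * pi))
    worst_near <- max(worst_near, max(abs(Gt - Gd)) / max(abs(Gd)))
  }
  expect_lt(worst_near, 1e-6)
  expect_lt(worst_far, 2e-3)
})

test_that("point-to-mesh distances match brute-force vertex distances", {
  pl <- rigid_platelet(center = c(1, 2, 3))
  m <- spheroid_surface(pl)
  set.seed(7)
  pts <- matrix(rnorm(30, sd = 3), ncol = 3) + rep(c(1, 2, 3), each = 10)
  d <- thromboflow:::point_mesh_distance_cpp(pts, m$vertices, m$triangles, -1)
  for (i in seq_len(nrow(pts))) {
    dv <- min(sqrt(colSums((t(m$vertices) - pts[i, ])^2)))
    expect_lte(d[i], dv + 1e-12)          # triangle distance <= vertex distance
    expect_gt(d[i], dv - 0.2)             # and not off by more than an edge
  }
})
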