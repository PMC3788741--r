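test_that("analysis/synthesis round-trips and is linear", {
  p <- 8
  s <- sphere_grid_surface(1, p)
  deg <- rep(0:p, times = 2 * (0:p) + 1)
  # unit sphere: only degree 0/1 coefficients
  expect_lt(max(abs(s$coef[deg > 1, ])), 1e-12)
  # round-trip of a random band-limited field
  set.seed(0)
  cf <- matrix(rnorm(3 * (p + 1)^2), ncol = 3)
  v <- sh_synthesize(cf, p)
  expect_lt(max(abs(sh_analyze(v, p) - cf)), 1e-12)
  # linearity
  cf2 <- matrix(rnorm(3 * (p + 1)^2), ncol = 3)
  expect_equal(sh_analyze(sh_synthesize(cf, p) + sh_synthesize(cf2, p), p),
               cf + cf2, tolerance = 1e-12)
  # grid shape mismatch refused
  expect_error(sh_analyze(v[-1, ], p), "grid shape")
})

test_that("upsampling is exact and downsampling is refused", {
  p <- 8
  s <- sphere_grid_surface(1, p)
  g16 <- surface_geometry(s, p_target = 16)
  expect_equal(g16$area, 4 * pi, tolerance = 1e-10)
  expect_error(sh_synthesize(s$coef, p, p_target = 6), "alias")
  # same-order evaluation reproduces analyzer input
  v <- sh_synthesize(s$coef, p)
  expect_lt(max(abs(sh_analyze(v, p) - s$coef)), 1e-12)
  # upsampling adds no spectral energy above degree p
  v16 <- sh_synthesize(s$coef, p, 16)
  cf16 <- sh_analyze(v16, 16)
  expect_lt(max(abs(cf16[((p + 1)^2 + 1):nrow(cf16), ])), 1e-12)
})

test_that("surface geometry reproduces sphere curvatures and Gauss-Bonnet", {
  s <- sphere_grid_surface(2, 12)
  g <- surface_geometry(s)
  expect_lt(max(abs(g$H - 0.5)), 1e-8)
  expect_lt(max(abs(g$K - 0.25)), 1e-8)
  expect_equal(g$area, 16 * pi, tolerance = 1e-8)
  # topological invariant on a randomly perturbed band-limited surface
  set.seed(1)
  deg <- rep(0:12, times = 2 * (0:12) + 1)
  cf <- s$coef
  pick <- deg >= 2 & deg <= 6
  cf[pick, ] <- cf[pick, ] + 0.02 * rnorm(sum(pick) * 3)
  gp <- surface_geometry(sh_surface(cf, 12), p_target = 24)
  expect_lt(abs(sum(gp$K * gp$dA) - 4 * pi), 1e-6 * 4 * pi)
})

test_that("spectral area error on an ellipsoid decays spectrally", {
  area_at <- function(p) {
    B <- thromboflow:::sh_basis_matrices(p, p)
    th <- acos(thromboflow:::gauss_legendre(p + 1)$x)
    ph <- 2 * pi * (seq_len(B$nph) - 1) / B$nph
    TH <- as.vector(outer(th, rep(1, B$nph)))
    PH <- as.vector(outer(rep(1, B$nth), ph))
    X <- cbind(1.5 * sin(TH) * cos(PH), sin(TH) * sin(PH), 0.7 * cos(TH))
    surface_geometry(sh_surface(sh_analyze(X, p), p), p_target = 2 * p)$area
  }
  a4 <- area_at(4); a8 <- area_at(8); a12 <- area_at(12); a16 <- area_at(16)
  e4 <- abs(a4 - a16); e8 <- abs(a8 - a16); e12 <- abs(a12 - a16)
  # faster than any power: successive ratios shrink
  expect_lt(e8 / e4, 0.1)
  expect_lt(e12 / e8, 0.25)
})

test_that("de-aliased products are exact for band-limited content", {
  p <- 8
  set.seed(2)
  # product of two degree-1 fields has exact degree <= 2 content:
  # symbolic oracle via explicit harmonics x and z (degree 1)
  B <- thromboflow:::sh_basis_matrices(p, p)
  th <- acos(thromboflow:::gauss_legendre(p + 1)$x)
  ph <- 2 * pi * (seq_len(B$nph) - 1) / B$nph
  TH <- as.vector(outer(th, rep(1, B$nph)))
  PH <- as.vector(outer(rep(1, B$nth), ph))
  f <- cbind(sin(TH) * cos(PH))     # x on the unit sphere
  g <- cbind(cos(TH))               # z
  cf <- sh_analyze(f, p); cg <- sh_analyze(g, p)
  prod_cf <- dealias_product(list(cf, cg), p,
                             function(v) v[[1]] * v[[2]])
  # oracle: x z = r^2 * (known degree-2 harmonic combination); evaluate
  # pointwise and analyze on a finer grid
  expected <- sh_truncate(sh_analyze(cbind(f * g), p), p, p)
  expect_equal(prod_cf, expected, tolerance = 1e-12)
  # linear op passes through unchanged
  lin <- dealias_product(list(cf), p, function(v) 3 * v[[1]])
  expect_equal(lin, 3 * cf, tolerance = 1e-12)
  # energy above degree p is identically zero after truncation
  expect_equal(nrow(prod_cf), (p + 1)^2)
})
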