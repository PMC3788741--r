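## Spectral (real spherical harmonic) representation of closed membranes:
## forward/inverse transforms, analytic surface differential geometry, and
## 3/2-rule de-aliasing.
##
## Conventions: real harmonics without the Condon-Shortley phase,
## fully normalized so that the basis is orthonormal on the unit sphere:
##   Y_{l,0}  = Pbar_l0(cos th) / sqrt(2 pi)
##   Y_{l,m}  = Pbar_lm(cos th) cos(m ph) / sqrt(pi)   (m > 0)
##   Y_{l,-m} = Pbar_lm(cos th) sin(m ph) / sqrt(pi)   (m > 0)
## with int_{-1}^{1} Pbar_lm^2 dx = 1.  The quadrature grid is
## Gauss-Legendre in cos(theta) ((p+1) nodes, poles excluded) times a
## uniform longitude grid (2p+2 nodes), which integrates products of two
## band-limited (degree <= p) fields exactly.

.sh_cache <- new.env(parent = emptyenv())

## Gauss-Legendre nodes/weights on (-1, 1) by Golub-Welsch.
gauss_legendre <- function(n) {
  if (n == 1) return(list(x = 0, w = 2))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- rev(e$values)
  w <- rev(2 * e$vectors[1, ]^2)
  list(x = x, w = w)
}

## Normalized associated Legendre values and theta-derivatives at nodes x.
## Returns list of matrices P[node, l-index] per m, but we assemble the full
## basis matrices directly instead.
sh_basis_matrices <- function(p_eval, p_grid) {
  key <- paste0("B", p_eval, "_", p_grid)
  if (!is.null(.sh_cache[[key]])) return(.sh_cache[[key]])
  gl <- gauss_legendre(p_grid + 1)
  x <- gl$x
  nth <- p_grid + 1
  nph <- 2 * p_grid + 2
  ph <- 2 * pi * (seq_len(nph) - 1) / nph
  sth <- sqrt(1 - x^2)
  cth <- x
  K <- (p_eval + 1)^2
  N <- nth * nph
  Y <- matrix(0, N, K); Yt <- matrix(0, N, K); Yp <- matrix(0, N, K)
  Ytt <- matrix(0, N, K); Ytp <- matrix(0, N, K); Ypp <- matrix(0, N, K)
  ## node ordering: theta-major, phi fastest
  kidx <- function(l, m) l * l + l + m + 1
  ## Pbar_lm over theta nodes for all l (vector per (l,m))
  for (m in 0:p_eval) {
    ## Pmm upward recursion
    P <- matrix(0, nth, p_eval + 1)        # columns l = m..p_eval mapped l+1
    if (m == 0) {
      Pmm <- rep(sqrt(0.5), nth)
    } else {
      Pmm <- rep(sqrt(0.5), nth)
      for (mm in seq_len(m)) Pmm <- sqrt((2 * mm + 1) / (2 * mm)) * sth * Pmm
    }
    P[, m + 1] <- Pmm
    if (m + 1 <= p_eval) P[, m + 2] <- sqrt(2 * m + 3) * cth * Pmm
    if (m + 2 <= p_eval) {
      for (l in (m + 2):p_eval) {
        al <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
        alm1 <- if (l - 1 > m) sqrt((4 * (l - 1)^2 - 1) / ((l - 1)^2 - m^2)) else NA
        bl <- if (l - 1 > m) al / alm1 else 0
        P[, l + 1] <- al * cth * P[, l] - bl * P[, l - 1]
      }
    }
    ## theta derivative: dP/dth = (l x Plm - e_lm P_{l-1,m}) / sin th
    ## (from (x^2-1) dP/dx = l x P_l - (l+m) P_{l-1}, x = cos th)
    dP <- matrix(0, nth, p_eval + 1)
    for (l in m:p_eval) {
      lowered <- if (l - 1 >= m) P[, l] else 0
      elm <- if (l - 1 >= m) sqrt((2 * l + 1) * (l^2 - m^2) / (2 * l - 1)) else 0
      dP[, l + 1] <- (l * cth * P[, l + 1] - elm * lowered) / sth
    }
    ## second derivative from the associated Legendre ODE
    d2P <- matrix(0, nth, p_eval + 1)
    for (l in m:p_eval) {
      d2P[, l + 1] <- -(cth / sth) * dP[, l + 1] -
        (l * (l + 1) - m^2 / sth^2) * P[, l + 1]
    }
    ## assemble basis columns via outer products with trig factors
    trigs <- if (m == 0) {
      list(list(sgn = 0, f = rep(1 / sqrt(2 * pi), nph), df = rep(0, nph)))
    } else {
      list(list(sgn = +1, f = cos(m * ph) / sqrt(pi),
                df = -m * sin(m * ph) / sqrt(pi)),
           list(sgn = -1, f = sin(m * ph) / sqrt(pi),
                df = m * cos(m * ph) / sqrt(pi)))
    }
    for (tg in trigs) {
      for (l in m:p_eval) {
        k <- kidx(l, tg$sgn * m)
        Y[, k] <- as.vector(t(outer(tg$f, P[, l + 1])))
        Yt[, k] <- as.vector(t(outer(tg$f, dP[, l + 1])))
        Ytt[, k] <- as.vector(t(outer(tg$f, d2P[, l + 1])))
        Yp[, k] <- as.vector(t(outer(tg$df, P[, l + 1])))
        Ytp[, k] <- as.vector(t(outer(tg$df, dP[, l + 1])))
        Ypp[, k] <- as.vector(t(outer(-m^2 * tg$f, P[, l + 1])))
      }
    }
  }
  w_full <- as.vector(t(outer(rep(2 * pi / nph, nph), gl$w)))
  theta <- acos(x)
  out <- list(Y = Y, Yt = Yt, Yp = Yp, Ytt = Ytt, Ytp = Ytp, Ypp = Ypp,
              w = w_full, p_eval = p_eval, p_grid = p_grid,
              nth = nth, nph = nph,
              theta_nodes = theta,
              sin_theta = as.vector(t(outer(rep(1, nph), sth))),
              degrees = rep(0:p_eval, times = 2 * (0:p_eval) + 1))
  .sh_cache[[key]] <- out
  out
}

#' Spherical-harmonic surface
#'
#' A closed membrane represented by three scalar fields (the Cartesian
#' coordinates) expanded in real spherical harmonics up to degree `p`.
#'
#' @param coef (p+1)^2 x 3 coefficient matrix
#' @param p spectral order
#' @return object of class `sh_surface`
#' @export
sh_surface <- function(coef, p) {
  stopifnot(nrow(coef) == (p + 1)^2, ncol(coef) == 3)
  structure(list(coef = as.matrix(coef), p = as.integer(p)),
            class = "sh_surface")
}

#' Forward spherical-harmonic transform
#'
#' Quadrature-exact analysis of grid values sampled on the order-`p`
#' Gauss-Legendre x uniform-longitude grid.  Values band-limited to degree
#' `p` round-trip through [sh_synthesize()] to machine precision.
#'
#' @param grid_values ((p+1)(2p+2)) x d matrix of per-node values
#'   (colatitude index fastest, longitude index slowest)
#' @param p spectral order of the grid
#' @return (p+1)^2 x d coefficient matrix
#' @export
sh_analyze <- function(grid_values, p) {
  B <- sh_basis_matrices(p, p)
  grid_values <- as.matrix(grid_values)
  if (nrow(grid_values) != B$nth * B$nph)
    stop("grid shape mismatch: expected ", B$nth * B$nph, " nodes for p = ", p)
  crossprod(B$Y, grid_values * B$w)
}

#' Inverse spherical-harmonic transform
#'
#' Evaluates a truncated expansion on the grid of order `p_target >= p`.
#' Upsampling is exact and adds no spectral energy; evaluating on a coarser
#' grid than the expansion order would alias and is refused.
#'
#' @param coef (p+1)^2 x d coefficients
#' @param p order of the expansion
#' @param p_target order of the evaluation grid (default `p`)
#' @return per-node values on the order-`p_target` grid
#' @export
sh_synthesize <- function(coef, p, p_target = p) {
  if (p_target < p)
    stop("refusing to evaluate on a coarser grid (p_target < p): would alias")
  B <- sh_basis_matrices(p, p_target)
  B$Y %*% as.matrix(coef)
}

## All six derivative syntheses at once (used by surface_geometry).
sh_synthesize_derivs <- function(coef, p, p_target = p) {
  B <- sh_basis_matrices(p, p_target)
  coef <- as.matrix(coef)
  list(X = B$Y %*% coef, Xt = B$Yt %*% coef, Xp = B$Yp %*% coef,
       Xtt = B$Ytt %*% coef, Xtp = B$Ytp %*% coef, Xpp = B$Ypp %*% coef,
       B = B)
}

#' Differential geometry of a spectral surface
#'
#' Analytic differentiation of the spherical-harmonic expansion (no finite
#' differences on the surface): first and second fundamental forms, outward
#' unit normals, mean curvature H (positive for a sphere: H = 1/r),
#' Gaussian curvature K, and per-node area elements whose sum is the
#' surface area.
#'
#' @param s an [sh_surface()]
#' @param p_target evaluation grid order (default: the surface order)
#' @return list with `nodes`, `normal`, `H`, `K`, `dA`, `area`, `volume`,
#'   metric terms `E`,`F`,`G`, `J` and the raw derivative fields
#' @export
surface_geometry <- function(s, p_target = s$p) {
  d <- sh_synthesize_derivs(s$coef, s$p, p_target)
  E <- rowSums(d$Xt * d$Xt); Fm <- rowSums(d$Xt * d$Xp)
  G <- rowSums(d$Xp * d$Xp)
  cr <- cbind(d$Xt[, 2] * d$Xp[, 3] - d$Xt[, 3] * d$Xp[, 2],
              d$Xt[, 3] * d$Xp[, 1] - d$Xt[, 1] * d$Xp[, 3],
              d$Xt[, 1] * d$Xp[, 2] - d$Xt[, 2] * d$Xp[, 1])
  J <- sqrt(rowSums(cr^2))
  W <- E * G - Fm^2
  if (any(W <= 1e-14 * max(W)))
    warning("near-degenerate surface metric (det -> 0)")
  nrm <- cr / J
  ## second fundamental form w.r.t. the *inward*-facing convention chosen so
  ## that a sphere has H = +1/r with outward normals
  L2 <- -rowSums(nrm * d$Xtt)
  M2 <- -rowSums(nrm * d$Xtp)
  N2 <- -rowSums(nrm * d$Xpp)
  H <- (E * N2 - 2 * Fm * M2 + G * L2) / (2 * W)
  K <- (L2 * N2 - M2^2) / W
  dA <- d$B$w * J / d$B$sin_theta
  vol <- sum(dA * rowSums(d$X * nrm)) / 3
  list(nodes = d$X, Xt = d$Xt, Xp = d$Xp, Xtt = d$Xtt, Xtp = d$Xtp,
       Xpp = d$Xpp, E = E, F = Fm, G = G, J = J, normal = nrm,
       H = H, K = K, dA = dA, area = sum(dA), volume = abs(vol),
       basis = d$B)
}

## Tangential (surface) gradient of per-node scalar fields, returned as
## Cartesian vectors.  `f` is an N x d matrix; the result is a list of d
## N x 3 matrices.  Derivatives are spectral; the combination with the
## inverse metric is pointwise, so no pole-singular field is ever analyzed.
surface_gradient <- function(f, geom, p_grid) {
  cf <- sh_analyze(as.matrix(f), p_grid)
  B <- sh_basis_matrices(p_grid, p_grid)
  ft <- B$Yt %*% cf; fp <- B$Yp %*% cf
  W <- geom$E * geom$G - geom$F^2
  lapply(seq_len(ncol(cf)), function(j) {
    a1 <- (geom$G * ft[, j] - geom$F * fp[, j]) / W
    a2 <- (geom$E * fp[, j] - geom$F * ft[, j]) / W
    a1 * geom$Xt + a2 * geom$Xp
  })
}

## Surface divergence of a per-node Cartesian vector field (N x 3), using
## div_G v = sum_a e_a . grad_G(v_a).  Valid for tangential and general
## fields (for a normal component f n it returns -2 H f automatically).
surface_divergence <- function(V, geom, p_grid) {
  gr <- surface_gradient(V, geom, p_grid)
  gr[[1]][, 1] + gr[[2]][, 2] + gr[[3]][, 3]
}

## Laplace-Beltrami of per-node scalar field(s) on the grid of order p_grid.
surface_laplacian <- function(f, geom, p_grid) {
  gr <- surface_gradient(cbind(f), geom, p_grid)[[1]]
  surface_divergence(gr, geom, p_grid)
}

#' De-aliased evaluation of a pointwise nonlinear operator
#'
#' Implements the 3/2-rule: the input fields are upsampled to order
#' ceil(3p/2), the operator is applied pointwise on the fine grid, and the
#' result is truncated back to order `p`.  Linear operators are unaffected;
#' quadratic nonlinearities are evaluated alias-free.
#'
#' @param coefs list of coefficient matrices (each (p+1)^2 x d_i)
#' @param p expansion order of the inputs
#' @param nonlinear_op function taking the per-node synthesized fields (as a
#'   list, same order) and returning a per-node matrix
#' @return coefficient matrix of the result, truncated to order `p`
#' @export
dealias_product <- function(coefs, p, nonlinear_op) {
  p2 <- ceiling(3 * p / 2)
  fine <- lapply(coefs, sh_synthesize, p = p, p_target = p2)
  vals <- nonlinear_op(fine)
  cf <- sh_analyze(as.matrix(vals), p2)
  sh_truncate(cf, p2, p)
}

#' Truncate coefficients to a lower order
#' @param coef coefficients at order `p_from`
#' @param p_from,p_to orders
#' @return coefficients at order `p_to`
#' @export
sh_truncate <- function(coef, p_from, p_to) {
  stopifnot(p_to <= p_from)
  keep <- rep(0:p_from, times = 2 * (0:p_from) + 1) <= p_to
  as.matrix(coef)[keep, , drop = FALSE]
}

## Pad coefficients with zeros up to a higher order.
sh_pad <- function(coef, p_from, p_to) {
  coef <- as.matrix(coef)
  out <- matrix(0, (p_to + 1)^2, ncol(coef))
  out[seq_len((p_from + 1)^2), ] <- coef
  out
}

#' Spectral energy per degree
#' @param coef coefficient matrix
#' @param p order
#' @return vector of summed squared coefficients for degrees 0..p
#' @export
sh_degree_energy <- function(coef, p) {
  deg <- rep(0:p, times = 2 * (0:p) + 1)
  sapply(0:p, function(l) sum(coef[deg == l, ]^2))
}

## Triangulation of an sh_surface for quadrature / distance queries:
## grid nodes plus two pole points (synthesized), fan caps at the poles.
sh_triangulate <- function(s, p_target = s$p) {
  B <- sh_basis_matrices(s$p, p_target)
  nodes <- sh_synthesize(s$coef, s$p, p_target)
  nth <- B$nth; nph <- B$nph
  ## pole values by direct basis evaluation at theta = 0, pi
  pole_vals <- sh_eval_points(s$coef, s$p, theta = c(1e-9, pi - 1e-9),
                              phi = c(0, 0))
  verts <- rbind(nodes, pole_vals)
  np <- nth * nph
  id <- function(i, j) ((j - 1L) %% nph) * nth + i
  tris <- list()
  for (i in seq_len(nth - 1)) {
    for (j in seq_len(nph)) {
      tris[[length(tris) + 1L]] <- c(id(i, j), id(i, j + 1L), id(i + 1L, j))
      tris[[length(tris) + 1L]] <- c(id(i, j + 1L), id(i + 1L, j + 1L),
                                     id(i + 1L, j))
    }
  }
  north <- np + 1L; south <- np + 2L
  for (j in seq_len(nph)) {
    tris[[length(tris) + 1L]] <- c(north, id(1L, j), id(1L, j + 1L))
    tris[[length(tris) + 1L]] <- c(south, id(nth, j + 1L), id(nth, j))
  }
  tri_mesh(verts, do.call(rbind, tris))
}

## Evaluate an expansion at arbitrary (theta, phi) points (slow path).
sh_eval_points <- function(coef, p, theta, phi) {
  stopifnot(length(theta) == length(phi))
  K <- (p + 1)^2
  out <- matrix(0, length(theta), ncol(coef))
  x <- cos(theta); sth <- sin(theta)
  kidx <- function(l, m) l * l + l + m + 1
  for (m in 0:p) {
    Pmm <- rep(sqrt(0.5), length(theta))
    if (m > 0) for (mm in seq_len(m)) Pmm <- sqrt((2 * mm + 1) / (2 * mm)) * sth * Pmm
    P <- matrix(0, length(theta), p + 1)
    P[, m + 1] <- Pmm
    if (m + 1 <= p) P[, m + 2] <- sqrt(2 * m + 3) * x * Pmm
    if (m + 2 <= p) for (l in (m + 2):p) {
      al <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
      alm1 <- sqrt((4 * (l - 1)^2 - 1) / ((l - 1)^2 - m^2))
      P[, l + 1] <- al * x * P[, l] - (al / alm1) * P[, l - 1]
    }
    for (l in m:p) {
      if (m == 0) {
        out <- out + (P[, l + 1] / sqrt(2 * pi)) %o% coef[kidx(l, 0), ]
      } else {
        out <- out + (P[, l + 1] * cos(m * phi) / sqrt(pi)) %o% coef[kidx(l, m), ]
        out <- out + (P[, l + 1] * sin(m * phi) / sqrt(pi)) %o% coef[kidx(l, -m), ]
      }
    }
  }
  out
}
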