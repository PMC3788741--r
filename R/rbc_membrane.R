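## RBC reference shape and elastic membrane tractions: Skalak-type in-plane
## law (weak shear resistance, strong resistance to areal dilatation) plus
## Helfrich bending at zero spontaneous curvature.
##
## Internal unit system: length um, time s, viscosity mPa s.  Membrane
## tension unit is then mPa um = 1e-9 N/m and bending modulus unit
## mPa um^3 = 1e-21 J.

#' Membrane elastic moduli
#'
#' @param Gs_uN_m in-plane shear modulus, micro-newton per meter
#'   (default 4.2, a standard literature value for the RBC membrane)
#' @param C dimensionless area-dilatation ratio; `C * Gs` resists area
#'   change, so C >> 1 makes the membrane nearly area-incompressible
#'   (default 100)
#' @param kb_J bending modulus, joule (default 2e-19)
#' @return object of class `membrane_moduli` with fields converted to
#'   internal units (`Gs` in mPa um, `kb` in mPa um^3)
#' @export
membrane_moduli <- function(Gs_uN_m = 4.2, C = 100, kb_J = 2e-19) {
  stopifnot(Gs_uN_m > 0, C > 0, kb_J >= 0)
  structure(list(Gs = 1000 * Gs_uN_m, C = C, kb = 1e21 * kb_J,
                 Gs_uN_m = Gs_uN_m, kb_J = kb_J),
            class = "membrane_moduli")
}

#' Biconcave discocyte reference surface
#'
#' The classic Evans-Fung resting shape,
#'   z(rho) = +/- (R0/2) sqrt(1 - rho^2/R0^2) *
#'            (0.207 + 2.003 rho^2/R0^2 - 1.123 rho^4/R0^4),
#' with rho = R0 sin(theta), projected onto order-p spherical harmonics.
#' The parameterization z(theta) = (R0/2) cos(theta) (0.207 + 2.003
#' sin^2 - 1.123 sin^4) is a degree-5 trigonometric polynomial, so the
#' projection is exact for p >= 5.
#'
#' @param p spectral order (>= 8 recommended for downstream mechanics)
#' @param R0 cell radius, um (default 3.91)
#' @return an [sh_surface()]
#' @export
biconcave_reference <- function(p, R0 = 3.91) {
  stopifnot(p >= 5)
  B <- sh_basis_matrices(p, p)
  th <- acos(gauss_legendre(p + 1)$x)
  ph <- 2 * pi * (seq_len(B$nph) - 1) / B$nph
  TH <- as.vector(outer(th, rep(1, B$nph)))
  PH <- as.vector(outer(rep(1, B$nth), ph))
  s2 <- sin(TH)^2
  z <- (R0 / 2) * cos(TH) * (0.207 + 2.003 * s2 - 1.123 * s2^2)
  X <- cbind(R0 * sin(TH) * cos(PH), R0 * sin(TH) * sin(PH), z)
  sh_surface(sh_analyze(X, p), p)
}

#' RBC state: current and reference membrane plus material parameters
#'
#' @param current,reference [sh_surface()] objects of equal order
#' @param moduli a [membrane_moduli()]
#' @param lambda interior/exterior viscosity ratio (bookkeeping; see the
#'   methods vignette for how it is treated in the flow solve)
#' @return object of class `rbc_state`
#' @export
rbc_state <- function(current, reference, moduli = membrane_moduli(),
                      lambda = 5) {
  stopifnot(current$p == reference$p)
  structure(list(current = current, reference = reference,
                 moduli = moduli, lambda = lambda),
            class = "rbc_state")
}

## Sign of the Helfrich bending traction in this package's curvature
## convention (H = +1/r for a sphere with outward normal; traction is the
## force the membrane exerts on the fluid).  Verified by the requirement
## that bending-driven relaxation decreases the Helfrich energy.
.bend_sign <- 1

#' Elastic membrane traction
#'
#' Computes the force per unit area the membrane exerts on the surrounding
#' fluid: in-plane Skalak-type tensions with principal values
#'   tau_i = (Gs/(l1 l2)) (l_i^2 (l_i^2 - 1) + C l1^2 l2^2 (l1^2 l2^2 - 1))
#' plus the Helfrich bending traction
#'   kb (Lap_s(2H) + 2H (2H^2 - 2K)) n
#' at zero spontaneous curvature.  All nonlinear products are evaluated on
#' the 3/2-dealiased grid and truncated back to order p.
#'
#' @param state an [rbc_state()]
#' @return list with `traction` (per-node force/area on the order-p grid,
#'   mPa), `coef` (its SH coefficients), principal stretches and tension
#'   diagnostics, and the current geometry
#' @export
elastic_traction <- function(state) {
  p <- state$current$p
  p2 <- ceiling(3 * p / 2)
  gr <- surface_geometry(state$reference, p_target = p2)
  gc <- surface_geometry(state$current, p_target = p2)
  Gs <- state$moduli$Gs; C <- state$moduli$C; kb <- state$moduli$kb

  detA <- gr$E * gr$G - gr$F^2
  deta <- gc$E * gc$G - gc$F^2
  ## mixed tensor M = A^-1 a; invariants of in-plane stretch
  tr_m <- (gr$G * gc$E - 2 * gr$F * gc$F + gr$E * gc$G) / detA
  det_m <- deta / detA
  if (any(det_m <= 1e-10 * stats::median(det_m)))
    stop("mesh inversion: non-positive principal stretch")
  Js <- sqrt(det_m)
  I1 <- tr_m - 2
  I2 <- det_m - 1
  dW1 <- (Gs / 2) * (I1 + 1)
  dW2 <- (Gs / 2) * (C * I2 - 1)
  ## contravariant tension T^{ab} = (2/Js) dW1 Ainv + 2 Js dW2 ainv
  c1 <- 2 * dW1 / Js
  c2 <- 2 * Js * dW2
  Ainv11 <- gr$G / detA; Ainv22 <- gr$E / detA; Ainv12 <- -gr$F / detA
  ainv11 <- gc$G / deta; ainv22 <- gc$E / deta; ainv12 <- -gc$F / deta
  T11 <- c1 * Ainv11 + c2 * ainv11
  T22 <- c1 * Ainv22 + c2 * ainv22
  T12 <- c1 * Ainv12 + c2 * ainv12
  ## Cartesian membrane stress S_aj = x_,al T^{al be} x_,be  (symmetric)
  S <- array(0, dim = c(nrow(gc$nodes), 3, 3))
  for (a in 1:3) for (j in 1:3) {
    S[, a, j] <- gc$Xt[, a] * (T11 * gc$Xt[, j] + T12 * gc$Xp[, j]) +
      gc$Xp[, a] * (T12 * gc$Xt[, j] + T22 * gc$Xp[, j])
  }
  f_inplane <- sapply(1:3, function(j)
    surface_divergence(S[, , j], gc, p2))

  if (kb > 0) {
    lap2H <- surface_laplacian(2 * gc$H, gc, p2)
    fb_n <- .bend_sign * kb *
      (lap2H + 2 * gc$H * (2 * gc$H^2 - 2 * gc$K))
    f_bend <- fb_n * gc$normal
  } else {
    f_bend <- 0 * gc$normal
  }
  f_tot <- f_inplane + f_bend
  cf <- sh_truncate(sh_analyze(f_tot, p2), p2, p)
  lam_max <- sqrt((tr_m + sqrt(pmax(tr_m^2 - 4 * det_m, 0))) / 2)
  lam_min <- Js / lam_max
  list(traction = sh_synthesize(cf, p), coef = cf,
       lambda1 = lam_max, lambda2 = lam_min, Js = Js,
       tension_iso = (T11 * gc$E + 2 * T12 * gc$F + T22 * gc$G) / 2,
       geometry_fine = gc)
}

#' Helfrich bending energy of a membrane
#' @param s an [sh_surface()]
#' @param kb bending modulus in internal units (mPa um^3)
#' @return energy in mPa um^3
#' @export
bending_energy <- function(s, kb) {
  p2 <- ceiling(3 * s$p / 2)
  g <- surface_geometry(s, p_target = p2)
  kb / 2 * sum((2 * g$H)^2 * g$dA)
}

#' Membrane area and enclosed volume
#' @param s an [sh_surface()]
#' @return list(area, volume, centroid)
#' @export
membrane_measures <- function(s) {
  g <- surface_geometry(s, p_target = ceiling(3 * s$p / 2))
  cen <- colSums(g$nodes * g$dA) / sum(g$dA)
  list(area = g$area, volume = g$volume, centroid = cen)
}

## Rescale a membrane about its centroid toward a target volume; the
## correction is capped (default 0.1% linear scale) per call.
rbc_renormalize <- function(s, target_volume, max_correction = 1e-3) {
  m <- membrane_measures(s)
  sc <- (target_volume / m$volume)^(1 / 3)
  sc <- min(max(sc, 1 - max_correction), 1 + max_correction)
  cf <- s$coef
  ## degree-0 coefficients carry the centroid; scale the shape about it
  cen0 <- cf[1, ]
  cf <- cf * sc
  cf[1, ] <- cen0
  sh_surface(cf, s$p)
}
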