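## Rigid oblate-spheroid platelet: collocation surface, pose updates by
## quaternion exponential map, and the wrapped orientation angle used by
## the flipping statistics.

#' Rigid spheroidal platelet
#'
#' An oblate spheroid with semi-axes (a_p, a_p, c_p); the default
#' 1.0 x 1.0 x 0.25 um matches the 2 um-diameter, aspect-ratio-0.25
#' platelet used in platelet adhesion dynamics modeling.  Pose is stored
#' as center + unit quaternion; at the identity orientation the minor
#' (c_p) axis points along +y, i.e. the platelet lies flat against a wall
#' at constant y.
#'
#' @param a_p equatorial semi-axis, um
#' @param c_p polar (minor) semi-axis, um
#' @param center 3-vector, um
#' @param quaternion unit quaternion (scalar first)
#' @param subdiv octasphere subdivision level for the collocation surface
#'   (8 * 4^subdiv faces; default 3 -> 512 faces)
#' @return object of class `rigid_platelet`
#' @export
rigid_platelet <- function(a_p = 1.0, c_p = 0.25,
                           center = c(0, 0, 0),
                           quaternion = quat_identity(),
                           subdiv = 3) {
  stopifnot(a_p > 0, c_p > 0)
  structure(list(a_p = a_p, c_p = c_p, center = as.numeric(center),
                 quaternion = quat_normalize(quaternion),
                 subdiv = as.integer(subdiv),
                 U = c(0, 0, 0), Omega = c(0, 0, 0)),
            class = "rigid_platelet")
}

## Body frame: minor axis along e3_body; identity pose maps e3_body -> +y.
.body_to_lab0 <- matrix(c(1, 0, 0,
                          0, 0, 1,
                          0, -1, 0), nrow = 3, byrow = TRUE)
## columns: image of ex, ey, ez(body); ez_body -> +y requires R0 %*% c(0,0,1) = (0,1,0)

#' Collocation surface of a platelet in world coordinates
#'
#' @param platelet a [rigid_platelet()]
#' @return a [tri_mesh()] of the posed spheroid
#' @export
spheroid_surface <- function(platelet) {
  ms <- octasphere(platelet$subdiv)
  v <- ms$vertices
  v <- cbind(platelet$a_p * v[, 1], platelet$a_p * v[, 2],
             platelet$c_p * v[, 3])
  Rm <- quat_to_matrix(platelet$quaternion) %*% .body_to_lab0
  vw <- v %*% t(Rm)
  vw <- sweep(vw, 2, platelet$center, "+")
  m <- tri_mesh(vw, ms$triangles)
  ## replace flat-triangle areas by curved (midpoint-lifted quadratic)
  ## areas so quadrature weights track the true spheroid surface measure
  curved <- spheroid_face_areas(ms, platelet$a_p, platelet$c_p)
  m$vert_weight <- m$vert_weight * 0
  third <- curved / 3
  for (k in 1:3) {
    tab <- tapply(third, ms$triangles[, k], sum)
    m$vert_weight[as.integer(names(tab))] <-
      m$vert_weight[as.integer(names(tab))] + tab
  }
  m$areas <- curved
  m
}

## Curved per-face areas of the scaled octasphere: each flat triangle is
## upgraded to a quadratic Lagrange triangle with edge midpoints lifted to
## the spheroid, integrated with a degree-4 rule.  O(h^4) accurate.
spheroid_face_areas <- function(ms, a_p, c_p) {
  scale <- c(a_p, a_p, c_p)
  v <- ms$vertices                      # on the unit sphere
  tr <- ms$triangles
  lift <- function(q) {
    q <- q / sqrt(rowSums(q^2))
    sweep(q, 2, scale, "*")
  }
  P1 <- sweep(v[tr[, 1], , drop = FALSE], 2, scale, "*")
  P2 <- sweep(v[tr[, 2], , drop = FALSE], 2, scale, "*")
  P3 <- sweep(v[tr[, 3], , drop = FALSE], 2, scale, "*")
  M12 <- lift((v[tr[, 1], ] + v[tr[, 2], ]) / 2)
  M23 <- lift((v[tr[, 2], ] + v[tr[, 3], ]) / 2)
  M13 <- lift((v[tr[, 1], ] + v[tr[, 3], ]) / 2)
  ## 6-point degree-4 rule on the reference triangle
  qp <- rbind(c(0.44594849091597, 0.44594849091597),
              c(0.44594849091597, 0.10810301816807),
              c(0.10810301816807, 0.44594849091597),
              c(0.09157621350977, 0.09157621350977),
              c(0.09157621350977, 0.81684757298046),
              c(0.81684757298046, 0.09157621350977))
  qw <- c(rep(0.22338158967801, 3), rep(0.10995174365532, 3)) / 2
  areas <- numeric(nrow(tr))
  nodes <- list(P1, P2, P3, M12, M23, M13)
  for (q in seq_len(nrow(qp))) {
    u <- qp[q, 1]; w <- qp[q, 2]; l1 <- 1 - u - w
    ## quadratic Lagrange shape-function derivatives (corner order
    ## lambda1 = 1-u-w, lambda2 = u, lambda3 = w)
    dNdu <- c(-(4 * l1 - 1), 4 * u - 1, 0, 4 * (l1 - u), 4 * w, -4 * w)
    dNdw <- c(-(4 * l1 - 1), 0, 4 * w - 1, -4 * u, 4 * u, 4 * (l1 - w))
    xu <- 0; xw <- 0
    for (k in 1:6) {
      xu <- xu + dNdu[k] * nodes[[k]]
      xw <- xw + dNdw[k] * nodes[[k]]
    }
    cr <- cbind(xu[, 2] * xw[, 3] - xu[, 3] * xw[, 2],
                xu[, 3] * xw[, 1] - xu[, 1] * xw[, 3],
                xu[, 1] * xw[, 2] - xu[, 2] * xw[, 1])
    areas <- areas + qw[q] * sqrt(rowSums(cr^2))
  }
  areas
}

#' Closed-form surface area of an oblate spheroid
#' @param a_p,c_p semi-axes with a_p >= c_p
#' @return area in um^2
#' @export
oblate_area <- function(a_p, c_p) {
  if (abs(a_p - c_p) < 1e-12 * a_p) return(4 * pi * a_p^2)
  e <- sqrt(1 - (c_p / a_p)^2)
  2 * pi * a_p^2 + pi * (c_p^2 / e) * log((1 + e) / (1 - e))
}

#' Advance a rigid pose by one time step
#'
#' Center moves with U; the orientation quaternion advances by the
#' exponential map of Omega * dt and is renormalized.
#'
#' @param platelet a [rigid_platelet()]
#' @param U translational velocity, um/s
#' @param Omega angular velocity, rad/s
#' @param dt time step, s
#' @return updated platelet
#' @export
update_pose <- function(platelet, U, Omega, dt) {
  stopifnot(dt > 0)
  platelet$center <- platelet$center + U * dt
  dq <- quat_from_rotvec(Omega * dt)
  platelet$quaternion <- quat_normalize(quat_multiply(dq, platelet$quaternion))
  platelet$U <- U
  platelet$Omega <- Omega
  platelet
}

#' Orientation angle about the x-axis
#'
#' Angle between the platelet's minor axis and the y-axis measured about
#' x, wrapped to (-pi/2, pi/2] because the spheroid is symmetric under
#' minor-axis reversal.  0 means flat against a constant-y wall; passing
#' pi/2 wraps to -pi/2 (the signature of a flipping event).
#'
#' @param platelet a [rigid_platelet()]
#' @return angle in radians in (-pi/2, pi/2]
#' @export
orientation_angle_x <- function(platelet) {
  Rm <- quat_to_matrix(platelet$quaternion) %*% .body_to_lab0
  minor <- Rm[, 3]                       # world direction of the c_p axis
  ang <- atan2(minor[3], minor[2])       # about x, from +y toward +z
  ang <- ang %% pi
  if (ang > pi / 2 + 1e-9) ang <- ang - pi
  ang
}
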