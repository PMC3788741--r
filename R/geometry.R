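## Vessel and thrombus geometry: parametric bump, wall triangulation,
## stenosis computation, near-wall probe curves.

#' Cylindrical vessel geometry
#'
#' A streamwise-periodic cylindrical arteriole segment.  The vessel axis is
#' +z, the cross-section is centered on (x = 0, y = 0), and all meshes built
#' from it are periodic in z with period `L`.
#'
#' @param R lumen radius in micrometers (default 7.5, i.e. a 15 um vessel)
#' @param L streamwise period in micrometers (default 45)
#' @return object of class `vessel_geometry`
#' @export
vessel_geometry <- function(R = 7.5, L = 45) {
  stopifnot(R > 0, L > 0)
  if (L <= 2 * R)
    warning("period L <= 2R: periodic images of the thrombus may interact")
  structure(list(R = R, L = L), class = "vessel_geometry")
}

#' Parametric thrombus bump
#'
#' The mural thrombus is a smooth bump protruding radially inward from the
#' +y side of the vessel wall.  In canonical (Gaussian) mode the protrusion
#' height is
#'   eta(x, z) = h * exp(-kappa * ((z - z_c)^2 / a + x^2 / b)),
#' so level sets are ellipses in the x-z plane, the x-y profile is Gaussian,
#' and the apex height is exactly `h`.  A literal mode
#'   eta = H - w^(kappa * ((z - z_c)^2/a + x^2/b))
#' is retained behind `mode = "literal"` for experimentation; its apex height
#' is H - 1 and it is not used by any default workflow.
#'
#' @param a streamwise spread parameter, um^2
#' @param b lateral spread parameter, um^2
#' @param h apex protrusion height, um (canonical mode)
#' @param z_c streamwise position of the apex, um
#' @param kappa dimensionless decay constant (default 1.9)
#' @param mode "gaussian" (canonical) or "literal"
#' @param H,w parameters of the literal form (ignored in canonical mode)
#' @return object of class `thrombus_shape`
#' @export
thrombus_shape <- function(a, b, h, z_c = 22.5, kappa = 1.9,
                           mode = c("gaussian", "literal"),
                           H = NULL, w = NULL) {
  mode <- match.arg(mode)
  stopifnot(a > 0, b > 0, h >= 0)
  if (mode == "literal" && (is.null(H) || is.null(w)))
    stop("literal mode requires H and w")
  structure(list(a = a, b = b, h = h, z_c = z_c, kappa = kappa,
                 mode = mode, H = H, w = w),
            class = "thrombus_shape")
}

#' Thrombus protrusion height
#'
#' Evaluates the bump protrusion eta(x, z).  `z` is taken modulo the vessel
#' period so the bump repeats with every periodic image; the nearest image
#' is used.
#'
#' @param x lateral coordinate(s), um
#' @param z streamwise coordinate(s), um
#' @param shape a [thrombus_shape()]
#' @param L streamwise period used for the modulo reduction (um)
#' @return protrusion height(s), um; `eta(0, z_c) = h`
#' @export
bump_height <- function(x, z, shape, L = 45) {
  dz <- (z - shape$z_c) %% L
  dz <- ifelse(dz > L / 2, dz - L, dz)
  u <- shape$kappa * (dz^2 / shape$a + x^2 / shape$b)
  if (shape$mode == "gaussian") {
    shape$h * exp(-u)
  } else {
    pmax(shape$H - shape$w^u, 0)
  }
}

## Protrusion as a function of azimuth (angle from +y, radians) and z, using
## circumferential arc length R*phi as the lateral coordinate so that the
## displaced surface stays smooth all the way around the vessel.
bump_height_azimuthal <- function(phi, z, shape, vessel) {
  phi <- (phi + pi) %% (2 * pi) - pi
  bump_height(vessel$R * phi, z, shape, L = vessel$L)
}

#' Build the triangulated vessel + thrombus wall
#'
#' Nodes of a structured cylinder grid are displaced radially inward by the
#' thrombus protrusion (bump on the +y side), then triangulated with
#' checkerboard-alternating diagonals so the mesh retains the mirror
#' symmetry about `z = z_c`.  Face normals point into the lumen.
#'
#' @param vessel a [vessel_geometry()]
#' @param shape a [thrombus_shape()]
#' @param n_theta number of azimuthal divisions (>= 16)
#' @param n_z number of streamwise divisions (>= 32, even recommended)
#' @return object of class `tri_mesh` with fields `vertices`, `triangles`,
#'   `areas`, `normals` (per face, pointing into the lumen), `vert_weight`
#'   (lumped per-vertex quadrature areas), `tags` ("wall" or "thrombus"
#'   per face)
#' @export
build_wall_mesh <- function(vessel, shape, n_theta = 32, n_z = 64) {
  stopifnot(n_theta >= 16, n_z >= 32)
  R <- vessel$R; L <- vessel$L
  phi <- 2 * pi * (seq_len(n_theta) - 1) / n_theta   # angle from +y
  z <- L * (seq_len(n_z) - 1) / n_z
  grid <- expand.grid(i = seq_len(n_theta), j = seq_len(n_z))
  ph <- phi[grid$i]; zz <- z[grid$j]
  eta <- bump_height_azimuthal(ph, zz, shape, vessel)
  if (any(eta >= R))
    stop("thrombus protrusion reaches the vessel axis; h too large")
  r <- R - eta
  verts <- cbind(x = r * sin(ph), y = r * cos(ph), z = zz)
  idx <- function(i, j) (((j - 1L) %% n_z) * n_theta + ((i - 1L) %% n_theta) + 1L)
  tris <- matrix(0L, nrow = 2 * n_theta * n_z, ncol = 3)
  t <- 0L
  for (j in seq_len(n_z)) {
    for (i in seq_len(n_theta)) {
      v00 <- idx(i, j);     v10 <- idx(i + 1L, j)
      v01 <- idx(i, j + 1L); v11 <- idx(i + 1L, j + 1L)
      if ((i + j) %% 2L == 0L) {
        tris[t + 1L, ] <- c(v00, v10, v11)
        tris[t + 2L, ] <- c(v00, v11, v01)
      } else {
        tris[t + 1L, ] <- c(v00, v10, v01)
        tris[t + 2L, ] <- c(v10, v11, v01)
      }
      t <- t + 2L
    }
  }
  m <- tri_mesh(verts, tris, periodic_z = L)
  ## orient normals into the lumen (toward the axis)
  cent <- m$centroids
  inward <- -cbind(cent[, 1], cent[, 2], 0)
  s <- rowSums(m$normals * inward)
  flip <- s < 0
  if (any(flip)) {
    tris[flip, ] <- tris[flip, c(1, 3, 2)]
    m <- tri_mesh(verts, tris, periodic_z = L)
    s <- rowSums(m$normals * (-cbind(m$centroids[, 1], m$centroids[, 2], 0)))
  }
  if (any(s <= 0))
    stop("inverted triangles in wall mesh: resolution too coarse for this h")
  eta_cent <- bump_height_azimuthal(atan2(cent[, 1], cent[, 2]),
                                    cent[, 3], shape, vessel)
  m$tags <- ifelse(eta_cent > 0.01 * max(shape$h, 1e-12), "thrombus", "wall")
  m$vessel <- vessel
  m$shape <- shape
  m
}

#' Triangle mesh constructor
#'
#' @param vertices n x 3 matrix of points (um)
#' @param triangles m x 3 integer matrix of 1-based vertex indices
#' @param periodic_z period in z or NULL for a closed non-periodic surface
#' @return `tri_mesh` object with per-face areas/normals/centroids and lumped
#'   per-vertex quadrature weights
#' @export
tri_mesh <- function(vertices, triangles, periodic_z = NULL) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  p1 <- vertices[triangles[, 1], , drop = FALSE]
  p2 <- vertices[triangles[, 2], , drop = FALSE]
  p3 <- vertices[triangles[, 3], , drop = FALSE]
  if (!is.null(periodic_z)) {      # unwrap triangles straddling the z-seam
    wrap <- function(pa, pref) {
      dz <- pa[, 3] - pref[, 3]
      pa[, 3] <- pa[, 3] - periodic_z * round(dz / periodic_z)
      pa
    }
    p2 <- wrap(p2, p1); p3 <- wrap(p3, p1)
  }
  e1 <- p2 - p1; e2 <- p3 - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  a2 <- sqrt(rowSums(cr^2))
  if (any(a2 / 2 <= 1e-6))
    stop("degenerate triangle (area <= 1e-6 um^2)")
  areas <- a2 / 2
  normals <- cr / a2
  centroids <- (p1 + p2 + p3) / 3
  vw <- numeric(nrow(vertices))
  third <- areas / 3
  for (k in 1:3) {
    tab <- tapply(third, triangles[, k], sum)
    vw[as.integer(names(tab))] <- vw[as.integer(names(tab))] + tab
  }
  structure(list(vertices = vertices, triangles = triangles,
                 areas = areas, normals = normals, centroids = centroids,
                 vert_weight = vw, periodic_z = periodic_z),
            class = "tri_mesh")
}

#' Total surface area of a triangle mesh
#' @param mesh a `tri_mesh`
#' @return area in um^2
#' @export
mesh_area <- function(mesh) sum(mesh$areas)

#' Percent area stenosis at the thrombus throat
#'
#' Integrates the lumen cross-sectional area blocked by the bump at
#' `z = z_c` (the area between the displaced wall and the undisturbed
#' circle), as a percentage of pi R^2.
#'
#' @param shape a [thrombus_shape()]
#' @param vessel a [vessel_geometry()]
#' @return percent blockage in `[0, 100)`
#' @export
area_stenosis <- function(shape, vessel) {
  f <- function(phi) {
    d <- bump_height_azimuthal(phi, shape$z_c, shape, vessel)
    vessel$R * d - d^2 / 2
  }
  blocked <- stats::integrate(f, -pi, pi, rel.tol = 1e-8,
                              subdivisions = 400L)$value
  100 * blocked / (pi * vessel$R^2)
}

## Blocked cross-sectional area (um^2) at arbitrary z; used for bump volume.
blocked_area_at <- function(z, shape, vessel) {
  vapply(z, function(zz) {
    f <- function(phi) {
      d <- bump_height_azimuthal(phi, zz, shape, vessel)
      vessel$R * d - d^2 / 2
    }
    stats::integrate(f, -pi, pi, rel.tol = 1e-7)$value
  }, numeric(1))
}

#' Lumen fluid volume with the thrombus excluded
#' @param vessel a [vessel_geometry()]
#' @param shape a [thrombus_shape()] or NULL for a clean tube
#' @return volume in um^3
#' @export
lumen_fluid_volume <- function(vessel, shape = NULL) {
  v0 <- pi * vessel$R^2 * vessel$L
  if (is.null(shape) || shape$h == 0) return(v0)
  vb <- stats::integrate(function(z) blocked_area_at(z, shape, vessel),
                         0, vessel$L, rel.tol = 1e-6,
                         subdivisions = 200L)$value
  v0 - vb
}

#' Major-axis length of the thrombus projection ellipse
#'
#' The Gaussian bump has unbounded support, so the footprint used for
#' trajectory normalization is the 1%-of-apex-height contour: an ellipse
#' with semi-axes sqrt(ln(100) a / kappa) in z and sqrt(ln(100) b / kappa)
#' in x.  Returns the full length of the larger axis.
#'
#' @param shape a [thrombus_shape()]
#' @return length in um
#' @export
projection_major_axis <- function(shape) {
  2 * sqrt(log(100) / shape$kappa * max(shape$a, shape$b))
}

#' Near-wall probe curves
#'
#' Curves along z that follow the local (thrombus-modified) wall at constant
#' normal distance `offset`, one per azimuth.  Azimuth 0 runs along the
#' thrombus centerline (+y side), azimuth pi along the opposite ("back")
#' side.
#'
#' @param vessel a [vessel_geometry()]
#' @param shape a [thrombus_shape()]
#' @param offset wall-normal distance, um (default 0.5)
#' @param azimuths vector of azimuth angles, radians, measured from +y
#' @param n number of samples along z
#' @return list of `probe_curve` objects with fields `points` (n x 3), `z`,
#'   `azimuth`, `offset`
#' @export
probe_curves <- function(vessel, shape, offset = 0.5,
                         azimuths = c(0, pi), n = 128) {
  stopifnot(offset > 0, offset < vessel$R)
  R <- vessel$R; L <- vessel$L
  z <- L * (seq_len(n) - 0.5) / n
  lapply(azimuths, function(phi0) {
    eta <- bump_height_azimuthal(phi0, z, shape, vessel)
    if (any(R - eta <= offset))
      stop("offset exceeds the local wall gap at azimuth ", phi0)
    ## surface X(phi, z) = ((R - eta) sin phi, (R - eta) cos phi, z);
    ## inward normal from the analytic tangents.
    hh <- 1e-5
    detadz <- (bump_height_azimuthal(phi0, z + hh, shape, vessel) -
               bump_height_azimuthal(phi0, z - hh, shape, vessel)) / (2 * hh)
    detadphi <- (bump_height_azimuthal(phi0 + hh, z, shape, vessel) -
                 bump_height_azimuthal(phi0 - hh, z, shape, vessel)) / (2 * hh)
    r <- R - eta
    sp <- sin(phi0); cp <- cos(phi0)
    ## X_phi = (-detadphi sin + r cos, -detadphi cos - r sin, 0)
    ## X_z   = (-detadz sin, -detadz cos, 1)
    xphi <- cbind(-detadphi * sp + r * cp, -detadphi * cp - r * sp,
                  rep(0, n))
    xz <- cbind(-detadz * sp, -detadz * cp, rep(1, n))
    nr <- cbind(xphi[, 2] * xz[, 3] - xphi[, 3] * xz[, 2],
                xphi[, 3] * xz[, 1] - xphi[, 1] * xz[, 3],
                xphi[, 1] * xz[, 2] - xphi[, 2] * xz[, 1])
    nr <- nr / sqrt(rowSums(nr^2))
    ## orient toward the axis (into the lumen)
    surf <- cbind(r * sp, r * cp, z)
    s <- rowSums(nr * (-cbind(surf[, 1], surf[, 2], 0)))
    nr <- nr * ifelse(s < 0, -1, 1)
    pts <- surf + offset * nr
    structure(list(points = pts, z = z, azimuth = phi0, offset = offset,
                   shape = shape, vessel = vessel),
              class = "probe_curve")
  })
}
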