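## Stenotic-flow statistics: dimensionless peak velocity, near-wall
## profiles and shear estimates, trajectory density and reversibility,
## deposition-potential maps, flipping events, fluctuation measures, and
## the clinical-comparison conversions.

#' Dimensionless peak velocity (DPV)
#'
#' Maximum z-velocity over a lumen sampling grid of the stenotic solution
#' divided by the maximum of a non-stenotic reference solution on the same
#' vessel and fluid settings.  The simulation analogue of clinical peak
#' systolic velocity ratios.
#'
#' @param stenotic_solution,reference_solution `bie_solution` objects
#' @param n_grid sampling grid dimensions c(nx, ny, nz)
#' @param shell boundary shell excluded from sampling, um
#' @return list(dpv, peak_stenotic, peak_reference)
#' @export
dpv <- function(stenotic_solution, reference_solution,
                n_grid = c(64, 64, 96), shell = 0.1) {
  ps <- peak_axial_velocity(stenotic_solution, n_grid, shell)
  pr <- peak_axial_velocity(reference_solution, n_grid, shell)
  list(dpv = ps / pr, peak_stenotic = ps, peak_reference = pr)
}

#' Peak axial velocity over a lumen sampling grid
#' @param solution a `bie_solution`
#' @param n_grid grid dimensions
#' @param shell excluded boundary shell, um
#' @return maximum v_z, um/s
#' @export
peak_axial_velocity <- function(solution, n_grid = c(64, 64, 96),
                                shell = 0.1) {
  R <- solution$wall$vessel$R; L <- solution$wall$vessel$L
  xs <- seq(-R, R, length.out = n_grid[1])
  ys <- seq(-R, R, length.out = n_grid[2])
  zs <- seq(0, L, length.out = n_grid[3] + 1)[seq_len(n_grid[3])]
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  keep <- pts[, 1]^2 + pts[, 2]^2 < (R - shell)^2
  pts <- pts[keep, , drop = FALSE]
  dw <- point_mesh_distance_cpp(pts, solution$wall$vertices,
                                solution$wall$triangles,
                                solution$wall$vessel$L)
  pts <- pts[dw >= shell, , drop = FALSE]
  ## chunked evaluation to bound memory
  peak <- -Inf
  for (i0 in seq(1, nrow(pts), by = 8192)) {
    i1 <- min(i0 + 8191, nrow(pts))
    u <- velocity_at(pts[i0:i1, , drop = FALSE], solution)
    peak <- max(peak, max(u[, 3]))
  }
  peak
}

#' Near-wall velocity profiles along probe curves
#'
#' @param solution a `bie_solution`
#' @param curves list of `probe_curve` objects from [probe_curves()]
#' @return list of data frames (z, speed, vz) per curve
#' @export
near_wall_profile <- function(solution, curves) {
  lapply(curves, function(cv) {
    u <- velocity_at(cv$points, solution)
    data.frame(z = cv$z, speed = sqrt(rowSums(u^2)), vz = u[, 3])
  })
}

#' Wall shear stress estimate from a near-wall speed
#'
#' tau = mu v / dy: the speed at wall distance dy divided by dy times the
#' viscosity (finite-offset estimate of the wall velocity gradient).
#'
#' @param v near-wall speed(s), um/s
#' @param dy wall offset, um
#' @param mu viscosity, mPa s
#' @return shear stress, mPa
#' @export
shear_estimate <- function(v, dy, mu) mu * v / dy

#' Platelet trajectory density versus relative z
#'
#' Implements the three-step procedure: (i) project all trajectories onto
#' the x-z plane; (ii) at each station z = Z', divide the number of
#' trajectories passing the station by their largest x-separation
#' (max(x) - min(x)); (iii) renormalize by the highest density.  Stations
#' are expressed in relative z: (z - z_c) scaled by the major-axis length
#' of the thrombus projection ellipse (1%-of-apex contour).
#'
#' @param trajs list of `trajectory` objects
#' @param shape a [thrombus_shape()]
#' @param n_stations number of z-stations
#' @param rel_range range of relative z to cover
#' @param y_limit exclusion threshold on y-fluctuation, um
#' @return data frame (rel_z, density, n_used) with attribute `excluded`
#'   (number of excluded trajectories)
#' @export
trajectory_density <- function(trajs, shape, n_stations = 61,
                               rel_range = c(-2, 2), y_limit = 2) {
  keep <- !vapply(trajs, function(tr) is_traj_excluded(tr, y_limit),
                  logical(1))
  excluded <- sum(!keep)
  trajs <- trajs[keep]
  if (length(trajs) < 2)
    stop("fewer than 2 trajectories remain after the y-fluctuation exclusion")
  axis_len <- projection_major_axis(shape)
  relz <- seq(rel_range[1], rel_range[2], length.out = n_stations)
  zq <- shape$z_c + relz * axis_len
  dens <- vapply(zq, function(zz) {
    xs <- vapply(trajs, function(tr) {
      if (zz < min(tr$z) || zz > max(tr$z)) return(NA_real_)
      approx(tr$z, tr$x, xout = zz, ties = "ordered")$y
    }, numeric(1))
    xs <- xs[!is.na(xs)]
    if (length(xs) < 2) return(NA_real_)
    spread <- max(xs) - min(xs)
    if (spread < 1e-9) return(Inf)
    length(xs) / spread
  }, numeric(1))
  finite <- is.finite(dens)
  if (!any(finite)) {
    ## degenerate but legitimate case: all trajectories identical spread
    dens[] <- 1
  } else {
    dens <- dens / max(dens[finite], na.rm = TRUE)
    dens[is.infinite(dens)] <- 1
  }
  structure(data.frame(rel_z = relz, density = dens,
                       n_used = length(trajs)),
            excluded = excluded)
}

#' Trajectory fore-aft reversibility
#'
#' Percent mismatch of the x-coordinate at stations equidistant upstream
#' and downstream of the thrombus center:
#'   Delta%(Z) = 100 |x(z_c + Z) - x(z_c - Z)| /
#'               max(|x(z_c - Z)|, 0.1 x_span).
#' For a non-monotone z-track (recirculation) the first crossing of each
#' station is used and the result is flagged.
#'
#' @param traj a `trajectory`
#' @param z_c thrombus center, um
#' @param stations vector of Z offsets, um
#' @return data frame (Z, delta_pct) with attribute `recirculation`
#' @export
reversibility <- function(traj, z_c, stations) {
  zz <- traj$z; xx <- traj$x
  recirc <- is.unsorted(zz)
  x_at <- function(zq) {
    if (zq < min(zz) || zq > max(zz)) return(NA_real_)
    if (!recirc) return(approx(zz, xx, xout = zq, ties = "ordered")$y)
    ## first crossing
    s <- sign(zz - zq)
    k <- which(s[-1] * s[-length(s)] <= 0)[1]
    if (is.na(k)) return(NA_real_)
    w <- (zq - zz[k]) / (zz[k + 1] - zz[k])
    xx[k] + w * (xx[k + 1] - xx[k])
  }
  x_span <- max(xx) - min(xx)
  delta <- vapply(stations, function(Z) {
    xd <- x_at(z_c + Z); xu <- x_at(z_c - Z)
    if (is.na(xd) || is.na(xu)) return(NA_real_)
    100 * abs(xd - xu) / max(abs(xu), 0.1 * max(x_span, 1e-12))
  }, numeric(1))
  structure(data.frame(Z = stations, delta_pct = delta),
            recirculation = recirc)
}

#' Platelet deposition-potential map
#'
#' For every wall vertex, the minimum over time and over runs of the
#' distance to the platelet surface; vertices closer than the reactive
#' threshold (the alphaIIb-beta3 / vWF trimolecular bond length, ~260 nm)
#' are flagged as reachable for deposition.
#'
#' @param runs list of `trajectory` objects carrying pose columns (qw..qz)
#' @param wall wall `tri_mesh`
#' @param platelet a [rigid_platelet()] defining shape/mesh resolution
#' @param d_react reactive threshold, um
#' @param frame_stride evaluate every k-th recorded frame
#' @return list(min_dist per wall vertex, reactive flags, global_min)
#' @export
deposition_map <- function(runs, wall, platelet = rigid_platelet(),
                           d_react = 0.26, frame_stride = 1L) {
  nv <- nrow(wall$vertices)
  md <- rep(Inf, nv)
  for (tr in runs) {
    frames <- seq(1, nrow(tr), by = frame_stride)
    for (i in frames) {
      pl <- platelet
      pl$center <- c(tr$x[i], tr$y[i], tr$z[i] %% wall$vessel$L)
      pl$quaternion <- c(tr$qw[i], tr$qx[i], tr$qy[i], tr$qz[i])
      m <- spheroid_surface(pl)
      d <- point_mesh_distance_cpp(wall$vertices, m$vertices, m$triangles,
                                   -1)
      ## account for the platelet's periodic image in z
      for (sh in c(-wall$vessel$L, wall$vessel$L)) {
        ms <- m$vertices; ms[, 3] <- ms[, 3] + sh
        d <- pmin(d, point_mesh_distance_cpp(wall$vertices, ms,
                                             m$triangles, -1))
      }
      md <- pmin(md, d)
    }
  }
  list(min_dist = md, reactive = md < d_react, global_min = min(md),
       d_react = d_react)
}

#' Flipping events from the wrapped orientation angle
#'
#' Events are wrap crossings of theta_x (jumps from +pi/2 to -pi/2);
#' the streamwise spacing of consecutive events is the flipping distance.
#'
#' @param theta_x wrapped angle series, radians
#' @param z streamwise positions (unwrapped), um
#' @param jump_threshold minimum |jump| treated as a wrap, radians
#' @return list(event_z, distances)
#' @export
flipping_events <- function(theta_x, z, jump_threshold = pi / 2) {
  d <- diff(theta_x)
  idx <- which(abs(d) > jump_threshold)
  event_z <- (z[idx] + z[idx + 1]) / 2
  list(event_z = event_z, distances = diff(event_z))
}

#' Velocity fluctuation amplitude as percent of the mean
#' @param series probe velocity time series, um/s
#' @return 100 * max|v - mean| / mean
#' @export
fluctuation_stats <- function(series) {
  m <- mean(series)
  100 * max(abs(series - m)) / abs(m)
}

#' Diameter-to-area stenosis conversion
#'
#' area% = 100 * factor * (d/100)^power, the composite conversion used to
#' compare carotid diameter-stenosis data with simulated area stenosis
#' (super-linear but below quadratic; the 0.63 factor absorbs rheology
#' differences across the two length scales).
#'
#' @param diameter_pct diameter stenosis, percent
#' @param power exponent (default 1.5)
#' @param factor adjustment factor (default 0.63)
#' @return area stenosis, percent
#' @export
stenosis_convert <- function(diameter_pct, power = 1.5, factor = 0.63) {
  100 * factor * (diameter_pct / 100)^power
}

#' Dimensionless in vivo peak velocity
#' @param v measured peak velocity, cm/s
#' @param v_ref non-stenotic reference velocity, cm/s (default 75)
#' @return v / v_ref
#' @export
dpv_invivo <- function(v, v_ref = 75) v / v_ref

#' Fit the power-law exponent of DPV versus stenosis
#' @param S percent area stenosis values
#' @param dpv_values DPV values (>= 1)
#' @return exponent of the fit dpv - 1 ~ S^e
#' @export
dpv_exponent <- function(S, dpv_values) {
  keep <- dpv_values > 1 & S > 0
  fit <- lm(log(dpv_values[keep] - 1) ~ log(S[keep]))
  unname(coef(fit)[2])
}
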