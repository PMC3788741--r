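## Synthetic fixtures: cell-count arithmetic, seeded RBC placement,
## analytic toy validation cases, and synthetic platelet-trajectory
## bundles with known convergence structure so the metrics stage is
## testable without the flow solver.

#' Number of RBCs for a target tube hematocrit
#'
#' round(hct * pi R^2 L / V_rbc).  With the defaults (15 um vessel, 45 um
#' period, 94 um^3 mean cell volume) a 10% hematocrit gives 8 cells.
#'
#' @param hct hematocrit as a fraction (0, 0.5)
#' @param vessel a [vessel_geometry()]
#' @param V_rbc single-cell volume, um^3
#' @return integer cell count
#' @export
rbc_count_for_hct <- function(hct, vessel = vessel_geometry(),
                              V_rbc = 94) {
  stopifnot(hct > 0, hct < 0.5)
  as.integer(round(hct * pi * vessel$R^2 * vessel$L / V_rbc))
}

#' Platelet count range for a concentration band
#'
#' Whole platelets that fit the concentration in the available fluid
#' volume: floor(conc * V).  Truncation (not rounding) is used so a
#' physiological 150,000-450,000 per uL band in the thrombus-free lumen
#' volume maps to 1-3 platelets.
#'
#' @param conc_low,conc_high concentrations, per uL
#' @param fluid_volume_uL available fluid volume, uL (e.g. from
#'   [lumen_fluid_volume()] converted with 1 um^3 = 1e-9 uL)
#' @return integer vector c(low, high)
#' @export
platelet_count_range <- function(conc_low, conc_high, fluid_volume_uL) {
  stopifnot(conc_low <= conc_high, fluid_volume_uL >= 0)
  c(as.integer(floor(conc_low * fluid_volume_uL)),
    as.integer(floor(conc_high * fluid_volume_uL)))
}

#' Seeded non-overlapping RBC placement
#'
#' Sequential rejection sampling of cell poses (center + rotation) inside
#' the lumen with pairwise surface separation and wall clearance of at
#' least `clearance`.  Reproducible for a given seed.
#'
#' @param n number of cells
#' @param vessel a [vessel_geometry()]
#' @param shape a [thrombus_shape()] or NULL
#' @param seed RNG seed
#' @param clearance minimum guaranteed separation, um
#' @param margin extra sampling margin on top of `clearance`, um (placed
#'   configurations satisfy separation >= clearance + margin, giving the
#'   dynamics head-room above the contact gate)
#' @param R0 cell radius used for the placement envelope, um
#' @param max_attempts rejection-sampling budget
#' @return list of poses: list(center, rotation (3x3))
#' @export
place_rbcs <- function(n, vessel = vessel_geometry(), shape = NULL,
                       seed = 0, clearance = 0.2, margin = 0.3, R0 = 3.91,
                       max_attempts = 10000) {
  clearance <- clearance + margin
  if (n == 0) return(list())
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  ref <- biconcave_reference(8, R0 = R0)
  nodes0 <- sh_synthesize(ref$coef, 8)
  poses <- list()
  placed_nodes <- list()
  attempts <- 0
  while (length(poses) < n) {
    attempts <- attempts + 1
    if (attempts > max_attempts)
      stop("RBC placement failed after ", max_attempts, " attempts")
    q <- quat_random()
    Rm <- quat_to_matrix(q)
    rmax <- vessel$R - clearance - 0.1
    ## sample center uniformly in the cylinder, biased slightly off-wall
    cen <- c(runif(1, -rmax, rmax), runif(1, -rmax, rmax),
             runif(1, 0, vessel$L))
    if (cen[1]^2 + cen[2]^2 > (rmax - 1)^2) next
    nodes <- nodes0 %*% t(Rm)
    nodes <- sweep(nodes, 2, cen, "+")
    rad <- sqrt(nodes[, 1]^2 + nodes[, 2]^2)
    eta <- if (!is.null(shape))
      bump_height_azimuthal(atan2(nodes[, 1], nodes[, 2]), nodes[, 3] %% vessel$L,
                            shape, vessel) else 0
    if (any(rad > vessel$R - eta - clearance)) next
    ok <- TRUE
    for (other in placed_nodes) {
      dz <- c(-vessel$L, 0, vessel$L)
      dmin <- Inf
      for (s in dz) {
        sh_nodes <- nodes; sh_nodes[, 3] <- sh_nodes[, 3] + s
        d2 <- min(outer(rowSums(sh_nodes^2), rowSums(other^2), "+") -
                    2 * sh_nodes %*% t(other))
        dmin <- min(dmin, sqrt(max(d2, 0)))
      }
      if (dmin < clearance) { ok <- FALSE; break }
    }
    if (!ok) next
    poses[[length(poses) + 1]] <- list(center = cen, rotation = Rm,
                                       quaternion = q)
    placed_nodes[[length(placed_nodes) + 1]] <- nodes
  }
  poses
}

#' Synthetic platelet-trajectory bundle
#'
#' Streamlines of an analytic incompressible channel-with-Gaussian-bump
#' flow: lateral positions contract as x(z) = x0 (1 - g exp(-kappa
#' (z - z_c)^2 / a)), mimicking the convergence/divergence of platelet
#' paths past a thrombus, plus optional smooth lateral noise.  The
#' ground-truth density peak is exactly at z = z_c.
#'
#' @param shape a [thrombus_shape()] (sets z_c, a, kappa and, through
#'   `g = h/(2R)`, the contraction strength)
#' @param n number of trajectories
#' @param noise_sd lateral noise amplitude, um
#' @param seed RNG seed
#' @param vessel a [vessel_geometry()]
#' @param n_samples samples per trajectory
#' @param y_base y level of the bundle (um); a few trajectories get large
#'   y-excursions when `include_excluded` to exercise the exclusion rule
#' @param include_excluded add 2 trajectories violating the 2 um rule
#' @return list of `trajectory` objects
#' @export
synthetic_trajectory_bundle <- function(shape, n, noise_sd = 0, seed = 0,
                                        vessel = vessel_geometry(),
                                        n_samples = 161,
                                        y_base = -0.6,
                                        include_excluded = FALSE) {
  stopifnot(n >= 2)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  z <- seq(0, vessel$L, length.out = n_samples)
  g <- min(shape$h / (2 * vessel$R), 0.9)
  contraction <- 1 - g * exp(-shape$kappa * (z - shape$z_c)^2 / shape$a)
  x0 <- seq(-2, 2, length.out = n)
  u_along <- 1 / contraction          # mass conservation in the model flow
  tt <- cumsum(c(0, diff(z) / ((u_along[-1] + u_along[-n_samples]) / 2 *
                                 1000)))
  out <- lapply(seq_len(n), function(i) {
    noise <- if (noise_sd > 0) {
      raw <- rnorm(n_samples, sd = noise_sd)
      stats::filter(raw, rep(1 / 9, 9), circular = TRUE)
    } else 0
    df <- data.frame(t = tt, x = x0[i] * contraction + as.numeric(noise),
                     y = y_base + 0.2 * sin(2 * pi * z / vessel$L + i),
                     z = z,
                     theta_x = rep(0, n_samples),
                     d_wall = rep(1, n_samples), d_rbc = rep(Inf, n_samples),
                     speed = u_along * 1000)
    as_trajectory(df, shape = shape)
  })
  if (include_excluded) {
    for (k in 1:2) {
      df <- data.frame(t = tt, x = 0.5 * k * contraction,
                       y = y_base + 2.5 * sin(2 * pi * z / vessel$L),
                       z = z, theta_x = 0, d_wall = 1, d_rbc = Inf,
                       speed = u_along * 1000)
      out[[length(out) + 1]] <- as_trajectory(df, shape = shape)
    }
  }
  out
}

#' Ready-to-run validation case configurations
#'
#' Each case returns a full configuration plus the analytic expectation it
#' should reproduce:
#' * `cell_free_tube`: Poiseuille profile, peak 2 U_mean.
#' * `sphere_array`: periodic simple-cubic array drag (dilute closed form).
#' * `spheroid_shear`: Jeffery rotation period 2 pi (r_e + 1/r_e) / gamma.
#' * `rbc_tube`: 8-cell Hct = 10% tube (qualitative expectations).
#' * `full_paper`: the full stenosed cellular configuration.
#'
#' @param case case name
#' @param phi solid fraction for `sphere_array`
#' @param r_e aspect ratio for `spheroid_shear`
#' @param seed seed recorded in the config
#' @return list(config or parameters, expectation description and value)
#' @export
toy_case <- function(case = c("cell_free_tube", "sphere_array",
                              "spheroid_shear", "rbc_tube", "full_paper"),
                     phi = 1e-3, r_e = 4, seed = 0) {
  case <- match.arg(case)
  switch(case,
    cell_free_tube = list(
      config = simulation_config(shape = thrombus_shape(7.5, 6, 0),
                                 hct = 0, seed = seed),
      expectation = list(what = "Poiseuille profile u(r) = 2 U (1 - r^2/R^2)",
                         peak = 2 * 1128, rel_tol = 0.02)),
    sphere_array = list(
      L = 20, phi = phi,
      a = (phi * 20^3 * 3 / (4 * pi))^(1 / 3),
      expectation = list(what = "dilute simple-cubic array drag ratio",
                         value = hashimoto_drag_ratio(phi), rel_tol = 0.01)),
    spheroid_shear = list(
      r_e = r_e, gamma = 1, box = c(20, 20, 20),
      expectation = list(what = "Jeffery period 2 pi (r_e + 1/r_e)/gamma",
                         value = 2 * pi * (r_e + 1 / r_e), rel_tol = 0.03)),
    rbc_tube = list(
      config = simulation_config(shape = thrombus_shape(7.5, 6, 0),
                                 hct = 0.10, seed = seed),
      expectation = list(what = "8 cells; blunted profile; fluctuations")),
    full_paper = list(
      config = simulation_config(shape = thrombus_shape(7.5, 6, 1.2),
                                 hct = 0.10,
                                 platelet_release = list(
                                   x = 1, y = release_height_midgap(
                                     thrombus_shape(7.5, 6, 1.2)), z = 4),
                                 seed = seed),
      expectation = list(what = "stenosed cellular reference configuration")))
}

#' Dilute simple-cubic sphere-array drag ratio (closed form)
#' @param phi solid volume fraction
#' @return F / (6 pi mu a U)
#' @export
hashimoto_drag_ratio <- function(phi) {
  1 / (1 - 1.7601 * phi^(1 / 3) + phi - 1.5593 * phi^2)
}

#' Simulated drag ratio for the periodic sphere array
#' @param phi solid volume fraction
#' @param L cubic box edge, um
#' @param subdiv sphere mesh subdivision
#' @param mu viscosity, mPa s
#' @return simulated F / (6 pi mu a U)
#' @export
sphere_array_drag_ratio <- function(phi = 1e-3, L = 20, subdiv = 3,
                                    mu = 1.2) {
  a <- (phi * L^3 * 3 / (4 * pi))^(1 / 3)
  fluid <- fluid_properties(mu = mu)
  params <- ewald_params(box = c(L, L, L), xi = 1.2)
  pl <- rigid_platelet(a_p = a, c_p = a, center = c(L, L, L) / 2,
                       subdiv = subdiv)
  sol <- assemble_and_solve(platelets = list(pl), fluid = fluid,
                            params = params,
                            drive = list(type = "prescribed", U = c(0, 0, 1)))
  unname(sol$force[3] / (6 * pi * mu * a))
}

#' Simulated Jeffery rotation period for a spheroid in simple shear
#'
#' The tilt-rate of an axisymmetric spheroid rotating about the vorticity
#' axis depends only on the tilt angle, so the period is computed as
#' T = 2 int_0^pi dtheta / thetadot with mobility solves at uniformly
#' spaced angles (periodic trapezoid rule).
#'
#' @param r_e aspect ratio (a_p / c_p)
#' @param gamma shear rate, 1/s
#' @param box periodic box, um
#' @param subdiv spheroid mesh subdivision
#' @param n_angles number of tilt angles sampled
#' @param mu viscosity, mPa s
#' @return rotation period, s
#' @export
jeffery_period <- function(r_e = 4, gamma = 1, box = c(20, 20, 20),
                           subdiv = 3, n_angles = 16, mu = 1.2) {
  fluid <- fluid_properties(mu = mu)
  params <- ewald_params(box = box, xi = 1.2)
  shear <- function(pts) cbind(0 * pts[, 1], 0 * pts[, 1], gamma * pts[, 2])
  th <- pi * (seq_len(n_angles) - 1) / n_angles
  thdot <- vapply(th, function(a) {
    pl <- rigid_platelet(1, 1 / r_e, center = box / 2,
                         quaternion = quat_from_rotvec(c(a, 0, 0)),
                         subdiv = subdiv)
    sol <- assemble_and_solve(platelets = list(pl), fluid = fluid,
                              params = params,
                              drive = list(type = "background", fun = shear))
    sol$platelets[[1]]$Omega[1]
  }, numeric(1))
  2 * sum((pi / n_angles) / abs(thdot))
}
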