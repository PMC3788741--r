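## Time integration and run orchestration: quasi-static Stokes solves,
## explicit advection of membrane nodes, platelet pose updates, separation
## gating with time-step backoff, and trajectory recording.

#' Simulation configuration
#'
#' A config plus a seed fully determines a run.
#'
#' @param vessel a [vessel_geometry()]
#' @param shape a [thrombus_shape()] (use h = 0 for a clean tube)
#' @param fluid a [fluid_properties()]
#' @param n_theta,n_z wall mesh resolution
#' @param hct hematocrit (RBC volume fraction); 0 disables cells
#' @param rbc_p spectral order of RBC membranes
#' @param moduli a [membrane_moduli()]
#' @param lambda interior/exterior viscosity ratio bookkeeping value
#' @param platelet_release list(x, y, z) initial platelet center (y in
#'   centered coordinates; see the release-height note in the vignette) or
#'   NULL for no platelet
#' @param platelet_subdiv platelet mesh subdivision level
#' @param max_disp maximum node displacement per step, um
#' @param dt_cap hard cap on the time step, s
#' @param t_end physical end time, s (alternative stop criterion)
#' @param travel_target stop after this much streamwise platelet travel, um
#' @param integrator "euler" (default) or "heun" for rigid-body advection
#' @param output_every record every k-th step
#' @param seed RNG seed (cell placement)
#' @param ewald an [ewald_params()]
#' @param gate minimum surface separation, um
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(vessel = vessel_geometry(),
                              shape = thrombus_shape(7.5, 6, 1.2),
                              fluid = fluid_properties(),
                              n_theta = 24, n_z = 48,
                              hct = 0, rbc_p = 6,
                              moduli = membrane_moduli(), lambda = 5,
                              platelet_release = NULL,
                              platelet_subdiv = 3,
                              max_disp = 0.05, dt_cap = Inf,
                              t_end = Inf, travel_target = 90,
                              integrator = c("euler", "heun"),
                              output_every = 1L, seed = 0L,
                              ewald = NULL, gate = 0.05) {
  integrator <- match.arg(integrator)
  if (is.null(ewald))
    ewald <- ewald_params(box = c(20, 20, vessel$L))
  stopifnot(hct >= 0, hct <= 0.5)
  if (shape$h >= 2 * vessel$R) stop("h >= vessel diameter")
  structure(list(vessel = vessel, shape = shape, fluid = fluid,
                 n_theta = n_theta, n_z = n_z, hct = hct, rbc_p = rbc_p,
                 moduli = moduli, lambda = lambda,
                 platelet_release = platelet_release,
                 platelet_subdiv = platelet_subdiv,
                 max_disp = max_disp, dt_cap = dt_cap, t_end = t_end,
                 travel_target = travel_target, integrator = integrator,
                 output_every = as.integer(output_every),
                 seed = as.integer(seed), ewald = ewald, gate = gate),
            class = "simulation_config")
}

#' Default platelet release height
#'
#' Mid-gap of the constricted section measured in centered coordinates:
#' y = -h/2, i.e. halfway between the thrombus apex (y = R - h) and the
#' opposite wall (y = -R), equals 0.5 (D - h) from the bottom wall.
#'
#' @param shape a [thrombus_shape()]
#' @return y coordinate, um
#' @export
release_height_midgap <- function(shape) -shape$h / 2

#' Initialize a simulation state
#' @param config a [simulation_config()]
#' @return state list (wall, cache, rbcs, platelets, t, ...)
#' @export
sim_init <- function(config) {
  wall <- build_wall_mesh(config$vessel, config$shape,
                          config$n_theta, config$n_z)
  cache <- stokes_cache(wall, config$fluid, config$ewald)
  rbcs <- list()
  if (config$hct > 0) {
    n <- rbc_count_for_hct(config$hct, config$vessel)
    poses <- place_rbcs(n, config$vessel, config$shape, seed = config$seed)
    ref <- biconcave_reference(config$rbc_p)
    rbcs <- lapply(poses, function(ps) {
      cf <- ref$coef %*% t(ps$rotation)
      cf[1, ] <- cf[1, ] + ps$center * sqrt(4 * pi)
      rbc_state(sh_surface(cf, config$rbc_p), ref,
                config$moduli, config$lambda)
    })
  }
  platelets <- list()
  if (!is.null(config$platelet_release)) {
    r <- config$platelet_release
    platelets <- list(rigid_platelet(center = c(r$x, r$y, r$z),
                                     subdiv = config$platelet_subdiv))
  }
  list(config = config, wall = wall, cache = cache, rbcs = rbcs,
       platelets = platelets, t = 0, nstep = 0L,
       z_unwrapped = if (length(platelets)) platelets[[1]]$center[3] else NA,
       ref_volumes = lapply(rbcs, function(cs)
         membrane_measures(cs$reference)$volume))
}

## Minimum separations in a state (platelet-wall, platelet-RBC, RBC-wall).
state_separations <- function(state) {
  L <- state$config$vessel$L
  out <- list(platelet_wall = Inf, platelet_rbc = Inf, rbc_wall = Inf,
              rbc_rbc = Inf)
  pl_mesh <- if (length(state$platelets))
    spheroid_surface(state$platelets[[1]]) else NULL
  if (!is.null(pl_mesh))
    out$platelet_wall <- min(point_mesh_distance_cpp(
      pl_mesh$vertices, state$wall$vertices, state$wall$triangles, L))
  cell_meshes <- lapply(state$rbcs, function(cs) sh_triangulate(cs$current))
  for (cm in cell_meshes) {
    out$rbc_wall <- min(out$rbc_wall, min(point_mesh_distance_cpp(
      cm$vertices, state$wall$vertices, state$wall$triangles, L)))
    if (!is.null(pl_mesh))
      out$platelet_rbc <- min(out$platelet_rbc, min(point_mesh_distance_cpp(
        pl_mesh$vertices, cm$vertices, cm$triangles, -1)))
  }
  if (length(cell_meshes) > 1) {
    for (i in seq_along(cell_meshes)) for (j in seq_along(cell_meshes)) {
      if (i >= j) next
      out$rbc_rbc <- min(out$rbc_rbc, min(point_mesh_distance_cpp(
        cell_meshes[[i]]$vertices, cell_meshes[[j]]$vertices,
        cell_meshes[[j]]$triangles, -1)))
    }
  }
  out
}

#' Advance the simulation by one step
#'
#' Sequence: elastic tractions -> Stokes solve -> advect membrane nodes
#' with the local fluid velocity -> advance the platelet pose -> reproject
#' (de-alias) membrane coefficients -> capped volume renormalization.
#' A separation-gate breach in the tentative state halves dt and retries
#' (up to 5 times).
#'
#' @param state state from [sim_init()]
#' @param dt time step, s, or NULL for automatic (displacement-capped)
#' @return updated state; the last solution and diagnostics are attached
#'   as `solution`, `dt_used`, `cell_velocity`
#' @export
sim_step <- function(state, dt = NULL) {
  cfg <- state$config
  cell_srcs <- lapply(state$rbcs, rbc_source)
  sol <- assemble_and_solve(state$wall, cell_srcs, state$platelets,
                            cfg$fluid, cfg$ewald,
                            drive = list(type = "flow_rate",
                                         U_mean = cfg$fluid$U_mean),
                            cache = state$cache, gate = cfg$gate)
  ## membrane node velocities
  ucell <- lapply(seq_along(state$rbcs), function(i)
    membrane_velocities(state, sol, cell_srcs, i))
  vmax <- 0
  for (u in ucell) vmax <- max(vmax, max(abs(u)))
  for (pl in sol$platelets) {
    vmax <- max(vmax, max(abs(pl$U)),
                max(abs(pl$Omega)) * max(state$platelets[[1]]$a_p, 1))
  }
  if (is.null(dt)) dt <- min(cfg$max_disp / max(vmax, 1e-12), cfg$dt_cap)

  for (attempt in 1:6) {
    tentative <- advance_state(state, sol, ucell, cell_srcs, dt)
    seps <- state_separations(tentative)
    if (min(unlist(seps)) >= cfg$gate || attempt == 6) break
    dt <- dt / 2
  }
  if (min(unlist(seps)) < cfg$gate)
    stop("separation gate breached even after dt backoff")
  tentative$solution <- sol
  tentative$dt_used <- dt
  tentative$cell_velocity <- ucell
  tentative$separations <- seps
  tentative
}

## velocity of membrane grid nodes of cell i (first np vertices of its
## triangulated source mesh)
membrane_velocities <- function(state, sol, cell_srcs, i) {
  cs <- cell_srcs[[i]]
  np <- nrow(cs$traction)
  tgt <- cs$mesh$vertices[seq_len(np), , drop = FALSE]
  tab <- sol$tab; mu <- sol$fluid$mu
  u <- sl_apply_near(tgt, rep(0L, np), sol$cache$surf, sol$wall_density,
                     tab, mu)
  for (pl in sol$platelets)
    u <- u + sl_apply_near(tgt, rep(0L, np), pl$surf,
                           matrix(pl$q, ncol = 3, byrow = TRUE), tab, mu)
  for (j in seq_along(cell_srcs)) {
    cj <- cell_srcs[[j]]
    tv <- if (j == i) seq_len(np) else rep(0L, np)
    u <- u + sl_apply_near(tgt, tv, cj$surf, cj$density, tab, mu,
                           same_mesh = (j == i))
  }
  u[, 3] <- u[, 3] + sol$U0
  u
}

advance_state <- function(state, sol, ucell, cell_srcs, dt) {
  cfg <- state$config
  new <- state
  ## membranes: advect grid nodes, apply the short-range wall/cell
  ## exclusion (the lubrication stand-in layered on the separation gate),
  ## reproject, renormalize volume
  all_nodes <- lapply(seq_along(state$rbcs), function(i)
    sh_synthesize(state$rbcs[[i]]$current$coef, state$rbcs[[i]]$current$p) +
      dt * ucell[[i]])
  push_on <- 2 * cfg$gate
  for (i in seq_along(state$rbcs)) {
    nodes <- all_nodes[[i]]
    ## wall exclusion: push offending nodes toward the axis
    dw <- point_mesh_distance_cpp(nodes, state$wall$vertices,
                                  state$wall$triangles, cfg$vessel$L)
    off <- dw < push_on
    if (any(off)) {
      rad <- sqrt(nodes[off, 1]^2 + nodes[off, 2]^2)
      push <- pmin(push_on - dw[off], cfg$max_disp)
      nodes[off, 1] <- nodes[off, 1] * (1 - push / rad)
      nodes[off, 2] <- nodes[off, 2] * (1 - push / rad)
    }
    ## cell-cell exclusion along the center-center direction
    for (j in seq_along(state$rbcs)) {
      if (j == i) next
      other <- sh_triangulate(state$rbcs[[j]]$current)
      dc <- point_mesh_distance_cpp(nodes, other$vertices,
                                    other$triangles, -1)
      offc <- dc < push_on
      if (any(offc)) {
        ci <- colMeans(nodes); cj <- colMeans(all_nodes[[j]])
        dir <- ci - cj; dir <- dir / max(sqrt(sum(dir^2)), 1e-9)
        push <- pmin(push_on - dc[offc], cfg$max_disp)
        nodes[offc, ] <- nodes[offc, ] +
          outer(push, dir)
      }
    }
    all_nodes[[i]] <- nodes
  }
  for (i in seq_along(state$rbcs)) {
    cf <- sh_analyze(all_nodes[[i]], state$rbcs[[i]]$current$p)
    snew <- sh_surface(cf, state$rbcs[[i]]$current$p)
    snew <- rbc_renormalize(snew, state$ref_volumes[[i]])
    new$rbcs[[i]]$current <- snew
  }
  ## platelet: Euler or Heun on (U, Omega)
  if (length(state$platelets)) {
    pl <- state$platelets[[1]]
    U1 <- sol$platelets[[1]]$U; Om1 <- sol$platelets[[1]]$Omega
    if (cfg$integrator == "heun") {
      mid <- update_pose(pl, U1, Om1, dt)
      sol2 <- assemble_and_solve(state$wall, cell_srcs, list(mid),
                                 cfg$fluid, cfg$ewald,
                                 drive = list(type = "flow_rate",
                                              U_mean = cfg$fluid$U_mean),
                                 cache = state$cache, gate = cfg$gate / 2)
      U1 <- (U1 + sol2$platelets[[1]]$U) / 2
      Om1 <- (Om1 + sol2$platelets[[1]]$Omega) / 2
    }
    plnew <- update_pose(pl, U1, Om1, dt)
    dz <- plnew$center[3] - pl$center[3]
    L <- cfg$vessel$L
    plnew$center[3] <- plnew$center[3] %% L
    new$z_unwrapped <- state$z_unwrapped + dz
    new$platelets <- list(plnew)
  }
  new$t <- state$t + dt
  new$nstep <- state$nstep + 1L
  new
}

#' Run a simulation and record the platelet trajectory
#'
#' Deterministic for a given config + seed.  Trajectories whose
#' y-fluctuation exceeds 2 um are flagged `excluded = TRUE` (mirroring the
#' depth-of-field exclusion applied to epifluorescence data).
#'
#' @param config a [simulation_config()]
#' @param progress print progress every 25 steps
#' @return object of class `trajectory`: data frame with columns t, x, y,
#'   z (unwrapped), theta_x, d_wall, d_rbc, speed, qw, qx, qy, qz and
#'   attributes (config, excluded flag, per-cell area/volume drift)
#' @export
run_simulation <- function(config, progress = FALSE) {
  state <- sim_init(config)
  rows <- list()
  areas0 <- lapply(state$rbcs, function(cs)
    membrane_measures(cs$current)$area)
  z0 <- if (length(state$platelets)) state$platelets[[1]]$center[3] else 0
  record <- function(state) {
    pl <- state$platelets[[1]]
    seps <- state$separations %||% state_separations(state)
    data.frame(t = state$t, x = pl$center[1], y = pl$center[2],
               z = state$z_unwrapped,
               theta_x = orientation_angle_x(pl),
               d_wall = seps$platelet_wall, d_rbc = seps$platelet_rbc,
               speed = sqrt(sum(pl$U^2)),
               qw = pl$quaternion[1], qx = pl$quaternion[2],
               qy = pl$quaternion[3], qz = pl$quaternion[4])
  }
  repeat {
    state <- sim_step(state)
    if (length(state$platelets) &&
        state$nstep %% config$output_every == 0L)
      rows[[length(rows) + 1L]] <- record(state)
    if (progress && state$nstep %% 25L == 0L)
      message("step ", state$nstep, " t=", signif(state$t, 4),
              " z=", signif(state$z_unwrapped, 5))
    done_travel <- length(state$platelets) &&
      (state$z_unwrapped - z0) >= config$travel_target
    if (done_travel || state$t >= config$t_end ||
        state$nstep >= 100000L) break
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(t = numeric(0))
  drift <- lapply(seq_along(state$rbcs), function(i) {
    m <- membrane_measures(state$rbcs[[i]]$current)
    c(area = m$area / areas0[[i]] - 1,
      volume = m$volume / state$ref_volumes[[i]] - 1)
  })
  structure(df, class = c("trajectory", "data.frame"),
            config = config, excluded = is_traj_excluded(df),
            drift = drift, final_state = state)
}

is_traj_excluded <- function(df, y_limit = 2) {
  if (!nrow(df)) return(FALSE)
  (max(df$y) - min(df$y)) > y_limit
}

#' Trajectory constructor (used by synthetic fixtures)
#' @param df data frame with at least t, x, y, z columns
#' @param ... attributes to attach
#' @return `trajectory` object
#' @export
as_trajectory <- function(df, ...) {
  stopifnot(all(c("t", "x", "y", "z") %in% names(df)))
  if (is.unsorted(df$t, strictly = TRUE))
    stop("trajectory time must be strictly increasing")
  structure(df, class = c("trajectory", "data.frame"),
            excluded = is_traj_excluded(df), ...)
}

#' Two-window stationarity check
#'
#' TRUE when the last two equal windows of the series have means within
#' 5% and variances within 20% of each other.
#'
#' @param series numeric vector
#' @param window window length (default: half the series)
#' @return logical
#' @export
stationarity_check <- function(series, window = floor(length(series) / 2)) {
  stopifnot(window >= 2, length(series) >= 2 * window)
  n <- length(series)
  w2 <- series[(n - window + 1):n]
  w1 <- series[(n - 2 * window + 1):(n - window)]
  m1 <- mean(w1); m2 <- mean(w2)
  v1 <- var(w1); v2 <- var(w2)
  scale_m <- max(abs(m1), abs(m2), 1e-300)
  ok_mean <- abs(m1 - m2) <= 0.05 * scale_m
  scale_v <- max(v1, v2)
  ok_var <- if (scale_v <= 1e-300) TRUE else (abs(v1 - v2) <= 0.20 * scale_v)
  ok_mean && ok_var
}
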