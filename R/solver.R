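## Periodic boundary-integral Stokes solver: single-layer densities on the
## wall and platelet collocation meshes, known elastic tractions on RBC
## membranes, rigid-body closure (force- and torque-free platelets), and an
## unknown mean-flow constant closed by a volumetric flow-rate constraint.

#' Fluid properties
#'
#' @param mu plasma viscosity, mPa s (default 1.2; 3.0 is the whole-blood
#'   value used only in the Reynolds-number check)
#' @param rho density, kg/m^3
#' @param U_mean target mean velocity, um/s
#' @param lambda default interior/exterior viscosity ratio for cells
#' @return object of class `fluid_properties`
#' @export
fluid_properties <- function(mu = 1.2, rho = 1000, U_mean = 1128,
                             lambda = 5) {
  stopifnot(mu > 0, rho > 0)
  structure(list(mu = mu, rho = rho, U_mean = U_mean, lambda = lambda),
            class = "fluid_properties")
}

#' Reynolds number of the tube flow
#'
#' Re = rho U D / mu with SI conversion from the package's um / mPa s units.
#'
#' @param U_mean mean velocity, um/s
#' @param D vessel diameter, um
#' @param mu viscosity, mPa s (use the whole-blood value 3.0 for the
#'   physiological estimate)
#' @param rho density, kg/m^3
#' @return dimensionless Reynolds number
#' @export
reynolds_number <- function(U_mean = 1128, D = 15, mu = 3.0, rho = 1000) {
  rho * (U_mean * 1e-6) * (D * 1e-6) / (mu * 1e-3)
}

## ---- source-surface bookkeeping -----------------------------------------

## A solver source: a triangulated surface whose per-vertex density either
## is unknown (wall, platelets) or known (RBC membranes).
make_surf <- function(mesh, name) {
  list(name = name, mesh = mesh, pts = mesh$vertices,
       w = mesh$vert_weight, n = nrow(mesh$vertices))
}

## Per-vertex outward/consistent normals (area-weighted face average).
vertex_normals <- function(mesh) {
  vn <- matrix(0, nrow(mesh$vertices), 3)
  fa <- mesh$normals * mesh$areas
  for (k in 1:3) {
    idx <- mesh$triangles[, k]
    for (d in 1:3) {
      acc <- tapply(fa[, d], idx, sum)
      vn[as.integer(names(acc)), d] <- vn[as.integer(names(acc)), d] + acc
    }
  }
  vn / sqrt(rowSums(vn^2))
}

## Dense single-layer block with near-singular corrections.
## tgt_vertex: 1-based map of target rows to source vertex indices (0 if the
## target is not a source vertex).
sl_block <- function(tgt, tgt_vertex, surf, tab, mu, same_mesh,
                     near_factor = 2.0, max_depth = 3) {
  M <- sl_matrix_cpp(tgt, surf$pts, surf$w, tab$box, tab$table, tab$dims,
                     mu, same_mesh)
  tr <- near_corr_cpp(tgt, as.integer(tgt_vertex), surf$pts,
                      surf$mesh$triangles, tab$box, mu, near_factor,
                      as.integer(max_depth))
  if (nrow(tr) > 0) {
    for (row in seq_len(nrow(tr))) {
      i <- tr[row, 1]; j <- tr[row, 2]
      M[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)] <-
        M[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)] +
        matrix(tr[row, 3:11], 3, 3, byrow = TRUE)
    }
  }
  M
}

## Matrix-free single-layer apply (with near corrections) of known density.
sl_apply_near <- function(tgt, tgt_vertex, surf, dens, tab, mu,
                          same_mesh = FALSE, near_factor = 2.0,
                          max_depth = 3) {
  u <- sl_apply_cpp(tgt, surf$pts, surf$w, dens, tab$box, tab$table,
                    tab$dims, mu, same_mesh)
  tr <- near_corr_cpp(tgt, as.integer(tgt_vertex), surf$pts,
                      surf$mesh$triangles, tab$box, mu, near_factor,
                      as.integer(max_depth))
  if (nrow(tr) > 0) {
    for (row in seq_len(nrow(tr))) {
      i <- tr[row, 1]; j <- tr[row, 2]
      u[i, ] <- u[i, ] + matrix(tr[row, 3:11], 3, 3, byrow = TRUE) %*% dens[j, ]
    }
  }
  u
}

## Rank-one shift that removes the single-layer null space (density
## proportional to the surface normal produces no flow).
nullspace_reg <- function(M, surf) {
  vn <- vertex_normals(surf$mesh)
  nv <- as.vector(t(vn * surf$w))
  nv <- nv / sqrt(sum(nv^2))
  sigma <- mean(abs(diag(M)))
  list(M = M + sigma * outer(nv, nv), nvec = nv, sigma = sigma)
}

## ---- flow-rate (flux) functional -----------------------------------------

## Quadrature over the lumen disk at plane z: Gauss-Legendre radial rule on
## [0, R - delta] plus a linear near-wall tail correction applied to the
## outermost ring.
disk_quadrature <- function(R, z, delta = 0.3, n_r = 24, n_phi = 32) {
  gl <- gauss_legendre(n_r)
  r <- (gl$x + 1) / 2 * (R - delta)
  wr <- gl$w / 2 * (R - delta)
  phi <- 2 * pi * (seq_len(n_phi) - 0.5) / n_phi
  pts <- cbind(as.vector(outer(r, cos(phi))), as.vector(outer(r, sin(phi))),
               z)
  w <- as.vector(outer(wr * r, rep(2 * pi / n_phi, n_phi)))
  outer_ring <- as.vector(outer(seq_len(n_r) == n_r, rep(TRUE, n_phi)))
  w[outer_ring] <- w[outer_ring] + pi * R * delta / n_phi
  list(pts = pts, w = w, z = z, area = sum(w))
}

## Linear functional giving the flux through a disk due to a surface's
## density: flux = f_row . q  (q stacked 3 per vertex).
flux_functional <- function(disk, surf, tab, mu) {
  M <- sl_block(disk$pts, rep(0L, nrow(disk$pts)), surf, tab, mu, FALSE)
  zrows <- seq(3, nrow(M), by = 3)
  as.vector(crossprod(M[zrows, , drop = FALSE], disk$w))
}

## Flux of an explicitly known velocity field sampled at disk points.
flux_of_field <- function(disk, uz) sum(disk$w * uz)

## ---- cache ----------------------------------------------------------------

#' Precompute the wall operator for repeated solves
#'
#' Builds the Ewald table, the wall self-interaction matrix (with
#' null-space regularization and LU factorization) and flow-rate
#' functionals on a set of reference planes.
#'
#' @param wall wall `tri_mesh` from [build_wall_mesh()]
#' @param fluid a [fluid_properties()]
#' @param params an [ewald_params()]
#' @param flux_planes z-positions of candidate flux planes
#' @return cache list used by [assemble_and_solve()]
#' @export
stokes_cache <- function(wall, fluid, params,
                         flux_planes = c(0, 11.25, 33.75)) {
  tab <- ewald_table(params)
  surf <- make_surf(wall, "wall")
  A <- sl_block(surf$pts, seq_len(surf$n), surf, tab, fluid$mu, TRUE)
  reg <- nullspace_reg(A, surf)
  lu <- lu_factor(reg$M)
  R <- wall$vessel$R
  disks <- lapply(flux_planes, function(z) disk_quadrature(R, z))
  frows <- lapply(disks, function(d) flux_functional(d, surf, tab, fluid$mu))
  list(tab = tab, surf = surf, Amat = reg$M, lu = lu, nvec = reg$nvec,
       fluid = fluid, params = params, wall = wall,
       disks = disks, frows = frows, flux_planes = flux_planes)
}

## LU factorization helpers (LAPACK via solve on a stored factorization).
lu_factor <- function(A) {
  qr(A, LAPACK = TRUE)
}
lu_solve <- function(f, b) {
  qr.coef(f, b)
}

## ---- main solver -----------------------------------------------------------

#' Assemble and solve the coupled Stokes boundary-integral problem
#'
#' Mixed formulation: unknown single-layer density on the wall (no-slip),
#' unknown density plus rigid-body velocities (U, Omega) on each platelet
#' closed by zero net force and torque, known elastic tractions on RBC
#' membranes entering as forcing, and an unknown uniform mean-flow constant
#' closed by the prescribed volumetric flow rate.  Without a wall the same
#' machinery solves mobility (`drive$type = "background"`) and resistance
#' (`drive$type = "prescribed"`) problems for validation cases.
#'
#' @param wall wall `tri_mesh` or NULL
#' @param rbcs list of [rbc_state()] objects (their tractions are computed
#'   here) or a list of precomputed `list(mesh, density)` sources
#' @param platelets list of [rigid_platelet()]
#' @param fluid a [fluid_properties()]
#' @param params an [ewald_params()]
#' @param drive list: `list(type = "flow_rate", U_mean)` for tube flow,
#'   `list(type = "background", fun)` for mobility in an ambient field,
#'   `list(type = "prescribed", U, Omega)` for resistance problems
#' @param cache optional [stokes_cache()] (required when `wall` is given)
#' @param gate minimum allowed surface separation, um
#' @param tol solver relative residual
#' @return object of class `bie_solution`
#' @export
assemble_and_solve <- function(wall = NULL, rbcs = list(), platelets = list(),
                               fluid = fluid_properties(),
                               params = ewald_params(), drive = NULL,
                               cache = NULL, gate = 0.05, tol = 1e-6) {
  if (!is.null(wall) && is.null(cache))
    cache <- stokes_cache(wall, fluid, params)
  tab <- if (!is.null(cache)) cache$tab else ewald_table(params)
  mu <- fluid$mu

  ## platelet collocation surfaces
  pl_surfs <- lapply(platelets, function(p) make_surf(spheroid_surface(p),
                                                      "platelet"))
  ## RBC membrane sources with known densities (tractions)
  cell_src <- lapply(rbcs, function(cs) {
    if (!is.null(cs$mesh)) return(cs)          # precomputed source
    rbc_source(cs)
  })

  ## separation gate
  if (!is.null(wall)) {
    for (ps in pl_surfs) {
      d <- min(point_mesh_distance_cpp(ps$pts, wall$vertices,
                                       wall$triangles, wall$vessel$L))
      if (d < gate) stop("separation gate violated (platelet-wall: ",
                         signif(d, 3), " um)")
    }
    for (csrc in cell_src) {
      d <- min(point_mesh_distance_cpp(csrc$mesh$vertices, wall$vertices,
                                       wall$triangles, wall$vessel$L))
      if (d < gate) stop("separation gate violated (cell-wall: ",
                         signif(d, 3), " um)")
    }
  }

  ## background velocity at a set of points
  u_bg <- function(pts) {
    if (!is.null(drive$fun)) drive$fun(pts) else matrix(0, nrow(pts), 3)
  }
  ## velocity induced by all known cell sources at points
  u_cells <- function(pts, tgt_vertex = rep(0L, nrow(pts))) {
    u <- matrix(0, nrow(pts), 3)
    for (csrc in cell_src)
      u <- u + sl_apply_near(pts, tgt_vertex, csrc$surf, csrc$density,
                             tab, mu)
    u
  }

  npl <- length(platelets)
  has_wall <- !is.null(wall)
  flow_rate_mode <- has_wall && (is.null(drive) || drive$type == "flow_rate")
  Umean <- if (flow_rate_mode) (drive$U_mean %||% fluid$U_mean) else 0

  if (!has_wall && npl > 0 && !is.null(drive) &&
      drive$type %in% c("background", "prescribed")) {
    return(solve_free_particles(pl_surfs, platelets, fluid, tab, drive, tol))
  }
  stopifnot(has_wall)

  nw <- cache$surf$n
  ## choose the flux plane farthest from any platelet
  plane_idx <- 1L
  if (npl > 0) {
    pz <- sapply(platelets, function(p) p$center[3])
    L <- wall$vessel$L
    dmin <- sapply(cache$flux_planes, function(z)
      min(abs((pz - z + L / 2) %% L - L / 2)))
    plane_idx <- which.max(dmin)
  }
  disk <- cache$disks[[plane_idx]]
  frow_w <- cache$frows[[plane_idx]]
  Q_target <- Umean * pi * wall$vessel$R^2

  rhs_w <- -(u_bg(cache$surf$pts) + u_cells(cache$surf$pts))
  rhs_w_vec <- as.vector(t(rhs_w))
  flux_cells <- if (length(cell_src) > 0)
    flux_of_field(disk, u_cells(disk$pts)[, 3]) else 0
  flux_bg <- flux_of_field(disk, u_bg(disk$pts)[, 3])

  if (npl == 0) {
    ## bordered solve: [A ez; frow area][q; U0] = [rhs; Q]
    ez <- rep(c(0, 0, 1), nw)
    Ai_rhs <- lu_solve(cache$lu, cbind(rhs_w_vec, ez))
    s <- disk$area - sum(frow_w * Ai_rhs[, 2])
    U0 <- (Q_target - flux_cells - flux_bg - sum(frow_w * Ai_rhs[, 1])) / s
    qw <- Ai_rhs[, 1] - U0 * Ai_rhs[, 2]
    sol <- build_solution(cache, tab, fluid, wall, qw, list(), platelets,
                          cell_src, U0, drive, residual = 0, iterations = 0L)
    return(sol)
  }

  ## ---- coupled wall + platelet GMRES ----
  np_dof <- sapply(pl_surfs, function(s) 3 * s$n)
  ## per-platelet blocks
  blocks <- list()
  for (k in seq_len(npl)) {
    ps <- pl_surfs[[k]]
    A_wp <- sl_block(cache$surf$pts, rep(0L, nw), ps, tab, mu, FALSE)
    A_pw <- sl_block(ps$pts, rep(0L, ps$n), cache$surf, tab, mu, FALSE)
    A_pp <- sl_block(ps$pts, seq_len(ps$n), ps, tab, mu, TRUE)
    regp <- nullspace_reg(A_pp, ps)
    f_p <- flux_functional(disk, ps, tab, mu)
    ## rigid-body coupling: E maps (U, Omega) to nodal velocities
    E <- matrix(0, 3 * ps$n, 6)
    rc <- sweep(ps$pts, 2, platelets[[k]]$center)
    for (i in seq_len(ps$n)) {
      E[(3 * i - 2):(3 * i), 1:3] <- diag(3)
      E[(3 * i - 2):(3 * i), 4:6] <-
        matrix(c(0, rc[i, 3], -rc[i, 2],
                 -rc[i, 3], 0, rc[i, 1],
                 rc[i, 2], -rc[i, 1], 0), 3, 3)
    }
    ## force/torque rows: W q = 0
    W <- matrix(0, 6, 3 * ps$n)
    for (i in seq_len(ps$n)) {
      W[1:3, (3 * i - 2):(3 * i)] <- diag(3) * ps$w[i]
      W[4:6, (3 * i - 2):(3 * i)] <-
        matrix(c(0, -rc[i, 3], rc[i, 2],
                 rc[i, 3], 0, -rc[i, 1],
                 -rc[i, 2], rc[i, 1], 0), 3, 3) * ps$w[i]
    }
    ## saddle preconditioner for [A_pp -E; W 0]
    S <- rbind(cbind(regp$M, -E), cbind(W, matrix(0, 6, 6)))
    blocks[[k]] <- list(A_wp = A_wp, A_pw = A_pw, A_pp = regp$M,
                        E = E, W = W, f_p = f_p, lu = lu_factor(S),
                        surf = ps)
  }
  rhs_p <- lapply(seq_len(npl), function(k) {
    ps <- pl_surfs[[k]]
    -(u_bg(ps$pts) + u_cells(ps$pts))
  })

  ntot <- 3 * nw + sum(np_dof) + 6 * npl + 1
  idx_w <- seq_len(3 * nw)
  idx_p <- list(); idx_uo <- list()
  off <- 3 * nw
  for (k in seq_len(npl)) {
    idx_p[[k]] <- off + seq_len(np_dof[k]); off <- off + np_dof[k]
    idx_uo[[k]] <- off + 1:6; off <- off + 6
  }
  idx_u0 <- ntot
  ez <- rep(c(0, 0, 1), nw)

  amul <- function(x) {
    qw <- x[idx_w]; U0 <- x[idx_u0]
    out <- numeric(ntot)
    rw <- reg_wall_mul(cache, qw) + U0 * ez
    fl <- sum(frow_w * qw) + U0 * disk$area
    for (k in seq_len(npl)) {
      qp <- x[idx_p[[k]]]; uo <- x[idx_uo[[k]]]
      rw <- rw + blocks[[k]]$A_wp %*% qp
      rp <- blocks[[k]]$A_pw %*% qw + blocks[[k]]$A_pp %*% qp -
        blocks[[k]]$E %*% uo + U0 * rep(c(0, 0, 1), length(qp) / 3)
      out[idx_p[[k]]] <- rp
      out[idx_uo[[k]]] <- blocks[[k]]$W %*% qp
      fl <- fl + sum(blocks[[k]]$f_p * qp)
    }
    out[idx_w] <- rw
    out[idx_u0] <- fl
    out
  }
  precond <- function(x) {
    out <- numeric(ntot)
    out[idx_w] <- lu_solve(cache$lu, x[idx_w])
    for (k in seq_len(npl)) {
      y <- lu_solve(blocks[[k]]$lu, c(x[idx_p[[k]]], x[idx_uo[[k]]]))
      out[idx_p[[k]]] <- y[seq_len(np_dof[k])]
      out[idx_uo[[k]]] <- y[np_dof[k] + 1:6]
    }
    out[idx_u0] <- x[idx_u0] / disk$area
    out
  }
  b <- numeric(ntot)
  b[idx_w] <- rhs_w_vec
  for (k in seq_len(npl)) b[idx_p[[k]]] <- as.vector(t(rhs_p[[k]]))
  b[idx_u0] <- Q_target - flux_cells - flux_bg
  res <- gmres_solve(amul, b, precond, tol = tol)
  if (!res$converged)
    stop("BIE solve did not converge: residual ", signif(res$residual, 3))
  x <- res$x
  qw <- x[idx_w]
  pl_out <- lapply(seq_len(npl), function(k) {
    list(q = x[idx_p[[k]]], U = x[idx_uo[[k]]][1:3],
         Omega = x[idx_uo[[k]]][4:6], surf = pl_surfs[[k]])
  })
  build_solution(cache, tab, fluid, wall, qw, pl_out, platelets, cell_src,
                 x[idx_u0], drive, res$residual, res$iterations)
}

## wall matrix multiply through the regularized dense matrix; kept as a
## closure-friendly helper (cache stores the matrix implicitly in the LU,
## so we keep an explicit copy for the matvec)
reg_wall_mul <- function(cache, qw) {
  if (is.null(cache$Amat))
    stop("internal: wall matrix missing from cache")
  cache$Amat %*% qw
}

## Known-density source from an RBC state: triangulated membrane plus
## per-vertex elastic traction (poles synthesized from the coefficients).
rbc_source <- function(state) {
  et <- elastic_traction(state)
  mesh <- sh_triangulate(state$current)
  tr_pole <- sh_eval_points(et$coef, state$current$p,
                            theta = c(1e-9, pi - 1e-9), phi = c(0, 0))
  dens <- rbind(et$traction, tr_pole)
  list(surf = make_surf(mesh, "rbc"), mesh = mesh, density = dens,
       traction = et$traction, state = state)
}

build_solution <- function(cache, tab, fluid, wall, qw, pl_out, platelets,
                           cell_src, U0, drive, residual, iterations) {
  nw <- cache$surf$n
  qmat <- matrix(qw, ncol = 3, byrow = TRUE)
  Fz <- sum(qmat[, 3] * cache$surf$w)
  if (length(cell_src) > 0)
    Fz <- Fz + sum(sapply(cell_src, function(cs)
      sum(cs$density[, 3] * cs$surf$w)))
  V <- prod(tab$box)
  structure(list(wall_density = qmat, platelets = pl_out,
                 platelet_states = platelets,
                 cells = cell_src, U0 = U0, Gz = -Fz / V,
                 fluid = fluid, wall = wall, cache = cache, tab = tab,
                 drive = drive, residual = residual,
                 iterations = iterations),
            class = "bie_solution")
}

## Mobility / resistance solves for wall-free validation cases.
solve_free_particles <- function(pl_surfs, platelets, fluid, tab, drive,
                                 tol) {
  mu <- fluid$mu
  stopifnot(length(pl_surfs) == 1)  # validation cases use one particle
  ps <- pl_surfs[[1]]
  A <- sl_block(ps$pts, seq_len(ps$n), ps, tab, mu, TRUE)
  reg <- nullspace_reg(A, ps)
  ub <- if (!is.null(drive$fun)) drive$fun(ps$pts) else matrix(0, ps$n, 3)
  if (drive$type == "prescribed") {
    Uimp <- matrix(rep(drive$U, ps$n), ncol = 3, byrow = TRUE)
    if (!is.null(drive$Omega)) {
      rc <- sweep(ps$pts, 2, platelets[[1]]$center)
      Uimp <- Uimp + t(apply(rc, 1, function(r) cross3(drive$Omega, r)))
    }
    rhs <- as.vector(t(Uimp - ub))
    q <- solve(reg$M, rhs)
    qm <- matrix(q, ncol = 3, byrow = TRUE)
    Fdrag <- colSums(qm * ps$w)
    rc <- sweep(ps$pts, 2, platelets[[1]]$center)
    Tdrag <- colSums(t(sapply(seq_len(ps$n), function(i)
      cross3(rc[i, ], qm[i, ]) * ps$w[i])))
    return(structure(list(platelets = list(list(q = q, U = drive$U,
                                                Omega = drive$Omega %||% c(0, 0, 0),
                                                surf = ps)),
                          platelet_states = platelets,
                          force = Fdrag, torque = Tdrag, U0 = 0,
                          fluid = fluid, tab = tab, cells = list(),
                          wall = NULL, drive = drive,
                          residual = 0, iterations = 0L),
                     class = "bie_solution"))
  }
  ## mobility: unknown q, U, Omega; force/torque free
  rc <- sweep(ps$pts, 2, platelets[[1]]$center)
  n3 <- 3 * ps$n
  E <- matrix(0, n3, 6); W <- matrix(0, 6, n3)
  for (i in seq_len(ps$n)) {
    E[(3 * i - 2):(3 * i), 1:3] <- diag(3)
    E[(3 * i - 2):(3 * i), 4:6] <- matrix(c(0, rc[i, 3], -rc[i, 2],
                                            -rc[i, 3], 0, rc[i, 1],
                                            rc[i, 2], -rc[i, 1], 0), 3, 3)
    W[1:3, (3 * i - 2):(3 * i)] <- diag(3) * ps$w[i]
    W[4:6, (3 * i - 2):(3 * i)] <- matrix(c(0, -rc[i, 3], rc[i, 2],
                                            rc[i, 3], 0, -rc[i, 1],
                                            -rc[i, 2], rc[i, 1], 0), 3, 3) *
      ps$w[i]
  }
  S <- rbind(cbind(reg$M, -E), cbind(W, matrix(0, 6, 6)))
  rhs <- c(as.vector(t(-ub)), rep(0, 6))
  y <- solve(S, rhs)
  structure(list(platelets = list(list(q = y[seq_len(n3)],
                                       U = y[n3 + 1:3],
                                       Omega = y[n3 + 4:6], surf = ps)),
                 platelet_states = platelets, U0 = 0, fluid = fluid,
                 tab = tab, cells = list(), wall = NULL, drive = drive,
                 residual = 0, iterations = 0L),
            class = "bie_solution")
}

#' Evaluate the velocity field at points in the lumen
#'
#' Post-processing evaluation of all layer potentials (wall, platelets,
#' cells) plus the mean-flow constant and any background field.  Points
#' closer than `near_gate` to a surface are flagged in the `near` attribute.
#'
#' @param points n x 3 matrix, um
#' @param solution a `bie_solution`
#' @param near_gate distance below which points are flagged, um
#' @return n x 3 velocity matrix (um/s) with attribute `near`
#' @export
velocity_at <- function(points, solution, near_gate = 0.1) {
  points <- matrix(as.numeric(points), ncol = 3)
  tab <- solution$tab; mu <- solution$fluid$mu
  u <- matrix(0, nrow(points), 3)
  near_flag <- rep(FALSE, nrow(points))
  zero_map <- rep(0L, nrow(points))
  if (!is.null(solution$wall)) {
    dens <- solution$wall_density
    u <- u + sl_apply_near(points, zero_map, solution$cache$surf, dens,
                           tab, mu)
    dw <- point_mesh_distance_cpp(points, solution$wall$vertices,
                                  solution$wall$triangles,
                                  solution$wall$vessel$L)
    near_flag <- near_flag | dw < near_gate
  }
  for (pl in solution$platelets) {
    dens <- matrix(pl$q, ncol = 3, byrow = TRUE)
    u <- u + sl_apply_near(points, zero_map, pl$surf, dens, tab, mu)
    dp <- point_mesh_distance_cpp(points, pl$surf$pts,
                                  pl$surf$mesh$triangles, -1)
    near_flag <- near_flag | dp < near_gate
  }
  for (cs in solution$cells) {
    u <- u + sl_apply_near(points, zero_map, cs$surf, cs$density, tab, mu)
    dc <- point_mesh_distance_cpp(points, cs$mesh$vertices,
                                  cs$mesh$triangles, -1)
    near_flag <- near_flag | dc < near_gate
  }
  u[, 3] <- u[, 3] + solution$U0
  if (!is.null(solution$drive$fun))
    u <- u + solution$drive$fun(points)
  attr(u, "near") <- near_flag
  u
}

#' Volumetric flow rate through a lumen cross-section
#' @param solution a `bie_solution` (tube problems)
#' @param z plane position, um
#' @return flow rate, um^3/s
#' @export
flow_rate_at <- function(solution, z) {
  disk <- disk_quadrature(solution$wall$vessel$R, z)
  u <- velocity_at(disk$pts, solution)
  flux_of_field(disk, u[, 3])
}
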