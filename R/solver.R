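## ---------------------------------------------------------------------------
## Semi-implicit ALE incompressible Navier-Stokes with equal-order P1-P1
## elements, SUPG/PSPG stabilization, nodal RIIS valve penalties, sigma-model
## LES viscosity, weak outlet pressures and an on/off aortic valve.
## SI units throughout (m, s, Pa, kg).
## ---------------------------------------------------------------------------

#' Fluid properties
#' @param rho density (kg/m^3), default 1.06e3 (blood).
#' @param mu dynamic viscosity (Pa s), default 3.5e-3.
#' @export
fluid_properties <- function(rho = 1.06e3, mu = 3.5e-3) {
  stopifnot(rho > 0, mu > 0)
  structure(list(rho = rho, mu = mu), class = "fluid_properties")
}

#' Parameters of the sigma-model LES closure
#' @param C model constant (default 1.5).
#' @param delta filter width (m); if `NULL`, the average mesh edge is used.
#' @export
les_params <- function(C = 1.5, delta = NULL) {
  stopifnot(C > 0, is.null(delta) || delta > 0)
  structure(list(C = C, delta = delta), class = "les_params")
}

## mu_sgs from sorted singular values (descending) of the velocity gradient.
musgs_from_sv <- function(sv, C, delta, rho) {
  s1 <- sv[, 1L]; s2 <- sv[, 2L]; s3 <- sv[, 3L]
  out <- numeric(length(s1))
  pos <- s1 > 0
  out[pos] <- rho * C * delta^2 *
    s3[pos] * (s1[pos] - s2[pos]) * (s2[pos] - s3[pos]) / s1[pos]^2
  pmax(out, 0)
}

#' Sigma-model subgrid viscosity
#'
#' `mu_sgs = rho C Delta^2 sigma3 (sigma1 - sigma2)(sigma2 - sigma3) /
#' sigma1^2` with `sigma1 >= sigma2 >= sigma3` the singular values of the
#' velocity gradient.  By construction it vanishes for two-dimensional or
#' axisymmetric states (`sigma3 = 0`), for pure shear, for rigid rotation
#' and for any uniform velocity field; cells with zero gradient return 0
#' (removable singularity).
#'
#' @param grad velocity gradient(s): a 3 x 3 matrix or an M x 9 matrix of
#'   row-major gradients (1/s).
#' @param les a [les_params()] with `delta` resolved (m).
#' @param rho density (kg/m^3).
#' @return vector of subgrid viscosities (Pa s).
#' @export
sigma_viscosity <- function(grad, les, rho) {
  if (is.null(les$delta)) stop("les_params delta must be set")
  if (is.matrix(grad) && all(dim(grad) == c(3L, 3L)))
    grad <- matrix(as.numeric(t(grad)), 1L, 9L)
  sv <- t(apply(grad, 1L, function(g) svd(matrix(g, 3L, 3L, byrow = TRUE))$d))
  if (nrow(grad) == 1L) sv <- matrix(sv, 1L, 3L)
  musgs_from_sv(sv, les$C, les$delta, rho)
}

#' Outlet pressure forcing and backflow treatment
#'
#' @param p_sigma1 atrial-outlet pressure: a constant (mmHg) or function of
#'   time (s) returning mmHg.  The healthy scenario uses a constant 10 mmHg.
#' @param p_sigma2 aortic-outlet pressure, same conventions.
#' @param backflow `"none"` or `"null_tangential"` (tangential velocity
#'   constrained to zero on the atrial outlet).
#' @export
boundary_forcing <- function(p_sigma1 = 10, p_sigma2 = 80,
                             backflow = c("none", "null_tangential")) {
  backflow <- match.arg(backflow)
  as_fun <- function(p) if (is.function(p)) p else function(t) p
  structure(list(p1 = as_fun(p_sigma1), p2 = as_fun(p_sigma2),
                 backflow = backflow),
            class = "boundary_forcing")
}

#' Tangential-velocity constraint dofs for an outlet
#'
#' For the `"null_tangential"` backflow treatment the two tangential velocity
#' components of every outlet node are constrained to zero; the outlet normal
#' must be axis-aligned (the normal component stays governed by the pressure
#' condition).
#'
#' @param nodes mesh nodes (any units).
#' @param faces outlet faces.
#' @param node_ids outlet node indices.
#' @param mode `"none"` or `"null_tangential"`.
#' @return integer dof offsets (component index 1..3 per node) as a
#'   two-column matrix `cbind(node, comp)`, or NULL.
#' @export
apply_backflow_control <- function(nodes, faces, node_ids, mode) {
  if (mode == "none" || length(node_ids) == 0L) return(NULL)
  fa <- face_normals_areas(nodes, faces)
  nrm <- colSums(fa$normal * fa$area)
  nrm <- nrm / sqrt(sum(nrm^2))
  ax <- which.max(abs(nrm))
  if (abs(nrm[ax]) < 0.99)
    stop("null-tangential backflow control requires an axis-aligned outlet normal")
  tang <- setdiff(1:3, ax)
  cbind(node = rep(node_ids, each = 2L), comp = rep(tang, length(node_ids)))
}

## Dirichlet elimination on COO triplets: rows of constrained dofs are
## replaced by identity, column contributions moved to the RHS.
dirichlet_triplets <- function(i, j, x, rhs, dofs, vals) {
  nd <- length(rhs)
  isfix <- logical(nd)
  isfix[dofs] <- TRUE
  vfix <- numeric(nd)
  vfix[dofs] <- vals
  keep_row <- !isfix[i]
  colfix <- isfix[j] & keep_row
  if (any(colfix)) {
    mv <- rowsum(x[colfix] * vfix[j[colfix]], i[colfix])
    ids <- as.integer(rownames(mv))
    rhs[ids] <- rhs[ids] - mv[, 1L]
  }
  keep <- keep_row & !isfix[j]
  i <- c(i[keep], dofs); j <- c(j[keep], dofs); x <- c(x[keep], rep(1, length(dofs)))
  rhs[dofs] <- vals
  list(i = i, j = j, x = x, rhs = rhs)
}

#' One semi-implicit Navier-Stokes step
#'
#' Advances velocity and pressure by one step on a given (already moved)
#' mesh: implicit viscous/pressure/RIIS terms, convection linearized at the
#' previous velocity relative to the ALE velocity, explicit sigma-model
#' viscosity, SUPG/PSPG stabilization, strong wall velocity, weak outlet
#' normal traction, and optional null-tangential constraint on the atrial
#' outlet.  Passing `dt = Inf` (or <= 0) solves the steady problem.
#'
#' @param nodes current mesh nodes (m).
#' @param tets tet connectivity.
#' @param u_old previous velocity (N x 3, m/s).
#' @param u_ale ALE mesh velocity (N x 3, m/s).
#' @param props [fluid_properties()].
#' @param dt time step (s); `Inf` or non-positive for a steady solve.
#' @param musgs_cell per-cell subgrid viscosity (Pa s).
#' @param riis_node nodal RIIS coefficient `sum_i (R_i/eps_i) delta_i`
#'   (volume quadrature of the smoothed layer; adequate when `eps` is
#'   resolved by the mesh).
#' @param riis_surf surface quadrature of the RIIS layer for `eps` below the
#'   mesh size: `list(elem, bary, w)` with containing elements, barycentric
#'   coordinates and weights `w_q = (R/eps) A_q` of sample points on the
#'   immersed surface.
#' @param tau_react optional per-cell reaction coefficient entering only the
#'   stabilization parameter (used with the nodal smoothed-delta quadrature).
#' @param gd_react optional per-cell reaction coefficient strengthening the
#'   grad-div stabilization near a closed membrane; defaults to the
#'   element-mean of `riis_node`.  The scenario driver zeroes it near a
#'   reconstructed regurgitant orifice so the channel conducts.
#' @param pspg_proj optional per-cell unit normals (M x 3; zero rows mean no
#'   projection): in those cells the PSPG gradients are projected onto the
#'   plane orthogonal to the normal, removing the artificial PSPG
#'   permeability across an immersed membrane while keeping the tangential
#'   pressure stabilization (see [riis_pspg_projection()]).
#' @param u_gamma prescribed immersed-surface velocity (N x 3; zero here).
#' @param wall_nodes,wall_values strong velocity constraints.
#' @param outlets list of `list(faces =, p_pa =)` weak pressure outlets.
#' @param extra_dirichlet optional `cbind(node, comp)` matrix of additional
#'   zero-velocity component constraints (backflow control).
#' @param supg,pspg,lsic stabilization switches (streamline, pressure and
#'   grad-div/least-squares-on-incompressibility terms).
#' @param p_old previous pressure (warm start for the Krylov solver).
#' @param solver `"auto"` (ILUT-BiCGSTAB with direct fallback),
#'   `"direct"` (sparse LU) or `"iterative"` (fail on stall).
#' @param precond_refresh rebuild the incomplete-LU preconditioner for this
#'   solve; `FALSE` reuses the previous one (the time-stepping loop refreshes
#'   periodically since the system drifts slowly with the mesh motion).
#' @return list `u` (N x 3), `p` (N).
#' @export
ns_step <- function(nodes, tets, u_old, u_ale, props, dt,
                    musgs_cell = NULL, riis_node = NULL, riis_surf = NULL,
                    tau_react = NULL, pspg_proj = NULL, gd_react = NULL,
                    u_gamma = NULL,
                    wall_nodes = integer(0), wall_values = NULL,
                    outlets = list(), extra_dirichlet = NULL,
                    supg = TRUE, pspg = TRUE, lsic = TRUE, p_old = NULL,
                    solver = c("auto", "direct", "iterative"),
                    precond_refresh = TRUE) {
  solver <- match.arg(solver)
  n <- nrow(nodes)
  if (is.null(musgs_cell)) musgs_cell <- numeric(nrow(tets))
  if (is.null(riis_node)) riis_node <- numeric(n)
  if (is.null(u_gamma)) u_gamma <- matrix(0, n, 3L)
  if (is.null(riis_surf))
    riis_surf <- list(elem = integer(0), bary = matrix(0, 0L, 4L), w = numeric(0))
  if (is.null(tau_react)) tau_react <- numeric(nrow(tets))
  if (is.null(pspg_proj)) pspg_proj <- matrix(0, nrow(tets), 3L)
  if (is.null(gd_react))
    gd_react <- (riis_node[tets[, 1L]] + riis_node[tets[, 2L]] +
                 riis_node[tets[, 3L]] + riis_node[tets[, 4L]]) / 4
  dt_eff <- if (!is.finite(dt) || dt <= 0) -1 else dt
  ## weak outlet pressure: traction -p n (assembled as an extra RHS)
  rhs_extra <- numeric(4L * n)
  for (ot in outlets) {
    fa <- face_normals_areas(nodes, ot$faces)
    for (a in 1:3) {
      contrib <- -ot$p_pa * fa$area / 3 * fa$normal[, a]
      for (v in 1:3) {
        ids <- (a - 1L) * n + ot$faces[, v]
        agg <- rowsum(contrib, ids)
        rhs_extra[as.integer(rownames(agg))] <- rhs_extra[as.integer(rownames(agg))] + agg[, 1L]
      }
    }
  }
  ## strong constraints
  dofs <- integer(0); vals <- numeric(0)
  if (length(wall_nodes)) {
    if (is.null(wall_values)) wall_values <- matrix(0, length(wall_nodes), 3L)
    for (a in 1:3) {
      dofs <- c(dofs, (a - 1L) * n + wall_nodes)
      vals <- c(vals, wall_values[, a])
    }
  }
  if (!is.null(extra_dirichlet) && nrow(extra_dirichlet)) {
    dd <- (extra_dirichlet[, 2L] - 1L) * n + extra_dirichlet[, 1L]
    new <- !(dd %in% dofs)
    dofs <- c(dofs, dd[new]); vals <- c(vals, rep(0, sum(new)))
  }
  if (!length(outlets)) {
    ## fully enclosed flow: the pressure is defined up to a constant (no
    ## stress boundary anywhere); pin one pressure dof to fix the gauge
    dofs <- c(dofs, 3L * n + 1L); vals <- c(vals, 0)
  }
  dup <- duplicated(dofs)
  dofs <- dofs[!dup]; vals <- vals[!dup]
  ## fused assembly + preconditioned Krylov (ILUT-BiCGSTAB, warm-started,
  ## cached preconditioner) with fallback to a sparse direct factorization
  guess <- c(as.numeric(u_old), if (is.null(p_old)) numeric(n) else p_old)
  guess[dofs] <- vals
  mode <- switch(solver, auto = 0L, direct = 1L, iterative = 2L)
  storage.mode(tets) <- "integer"
  it <- cpp_ns_solve(nodes, tets, u_old, u_ale, musgs_cell, riis_node,
                     u_gamma, props$rho, props$mu, dt_eff, supg, pspg, lsic,
                     as.integer(riis_surf$elem), riis_surf$bary, riis_surf$w,
                     tau_react, pspg_proj, gd_react,
                     as.integer(dofs - 1L), as.numeric(vals), rhs_extra,
                     guess, tol = 1e-8, maxit = 300L, fill = 12,
                     droptol = 1e-4, refresh = precond_refresh,
                     solver_mode = mode)
  sol <- it$x
  if (any(!is.finite(sol)))
    stop("linear solver produced non-finite values (NaN check failed)")
  out <- list(u = matrix(sol[seq_len(3L * n)], n, 3L), p = sol[3L * n + seq_len(n)])
  attr(out, "solver_info") <- c(iterations = it$iterations, fallback = it$fallback)
  out
}

#' Steady flow solve by Picard iteration
#'
#' Repeats [ns_step()] in steady mode with the convection velocity frozen at
#' the previous iterate until the velocity increment stalls.
#'
#' @inheritParams ns_step
#' @param max_iter,tol Picard controls.
#' @export
ns_steady <- function(nodes, tets, props, wall_nodes, wall_values = NULL,
                      outlets = list(), riis_node = NULL, riis_surf = NULL,
                      tau_react = NULL, pspg_proj = NULL,
                      extra_dirichlet = NULL, max_iter = 8L, tol = 1e-8,
                      supg = TRUE, pspg = TRUE) {
  n <- nrow(nodes)
  u <- matrix(0, n, 3L)
  uale <- matrix(0, n, 3L)
  res <- NULL
  for (k in seq_len(max_iter)) {
    res <- ns_step(nodes, tets, u, uale, props, dt = Inf,
                   riis_node = riis_node, riis_surf = riis_surf,
                   tau_react = tau_react, pspg_proj = pspg_proj,
                   wall_nodes = wall_nodes, wall_values = wall_values,
                   outlets = outlets, extra_dirichlet = extra_dirichlet,
                   supg = supg, pspg = pspg)
    delta <- max(abs(res$u - u))
    u <- res$u
    if (delta < tol * max(max(abs(u)), 1e-12)) break
  }
  res
}

#' Aortic valve on/off controller
#'
#' Opening is instantaneous and triggered by the first positive
#' ventricle-aorta pressure jump; closure occurs at the first negative flow
#' rate at the aortic valve plane while open.  A single open and a single
#' close event are allowed per systole; a re-opening request is rejected and
#' logged.
#'
#' @param state initial state (`"open"` for the healthy scenario, which
#'   starts just after the opening with `t_o = 0`; `"closed"` for the
#'   regurgitant scenarios).
#' @param t0 initial time.
#' @return object of class `aortic_valve_controller` with fields `state`,
#'   `t_open`, `t_close`, `log`.
#' @export
aortic_valve_controller <- function(state = c("closed", "open"), t0 = 0) {
  state <- match.arg(state)
  structure(list(state = state,
                 t_open = if (state == "open") t0 else NA_real_,
                 t_close = NA_real_, seen_forward = FALSE,
                 log = character(0)),
            class = "aortic_valve_controller")
}

#' @rdname aortic_valve_controller
#' @param ctrl the controller.
#' @param p_vent,p_aorta slice-averaged pressures (Pa) below/above the valve.
#' @param q_aortic flow rate at the aortic valve plane (m^3/s, outflow > 0).
#' @param t current time (s).
#' @param q_tol closure tolerance (m^3/s): the valve closes when a negative
#'   aortic flow rate develops, i.e. once forward ejection has been observed
#'   (`q > q_tol` at some earlier step) and the flow then drops below
#'   `-q_tol`; the guard keeps sign noise during the initial pressurization
#'   transient (null initial condition) from triggering a spurious closure.
#' @export
update_aortic_valve <- function(ctrl, p_vent, p_aorta, q_aortic, t, q_tol = 1e-6) {
  if (ctrl$state == "closed") {
    if (is.na(ctrl$t_open) && p_vent - p_aorta > 0) {
      ctrl$state <- "open"
      ctrl$t_open <- t
      ctrl$log <- c(ctrl$log, sprintf("open at t=%g", t))
    } else if (!is.na(ctrl$t_open) && p_vent - p_aorta > 0) {
      ctrl$log <- c(ctrl$log, sprintf("re-opening rejected at t=%g", t))
    }
  } else if (ctrl$state == "open") {
    if (q_aortic > q_tol) ctrl$seen_forward <- TRUE
    if (ctrl$seen_forward && q_aortic < -q_tol) {
      ctrl$state <- "closed"
      ctrl$t_close <- t
      ctrl$log <- c(ctrl$log, sprintf("close at t=%g", t))
    }
  }
  ctrl
}

#' Flux of a nodal velocity field through boundary faces
#' @param nodes mesh nodes.
#' @param u nodal velocity (N x 3).
#' @param faces outward-oriented boundary triangles.
#' @return total flux (volume/time in the mesh units).
#' @export
boundary_flux <- function(nodes, u, faces) {
  fa <- face_normals_areas(nodes, faces)
  uf <- (u[faces[, 1L], , drop = FALSE] + u[faces[, 2L], , drop = FALSE] +
         u[faces[, 3L], , drop = FALSE]) / 3
  sum(rowSums(uf * fa$normal) * fa$area)
}

#' Surface quadrature of the RIIS layer
#'
#' Samples an immersed valve surface at the centroids of a midpoint 4-fold
#' subdivision of its triangles and locates the samples in the fluid mesh.
#' The weights `w_q = (R/eps) A_q` make the assembled term the consistent
#' evaluation of the smoothed-delta penalty when `eps` is below the mesh
#' size (its across-layer integral is 1, so the layer collapses onto the
#' surface).
#'
#' @param vnodes,vtris valve surface (same units as the mesh).
#' @param nodes,tets fluid mesh.
#' @param R,eps RIIS resistance and half-thickness.
#' @return list `elem`, `bary`, `w` for [ns_step()]'s `riis_surf`.
#' @export
riis_surface_quadrature <- function(vnodes, vtris, nodes, tets, R, eps) {
  A <- vnodes[vtris[, 1L], , drop = FALSE]
  B <- vnodes[vtris[, 2L], , drop = FALSE]
  C <- vnodes[vtris[, 3L], , drop = FALSE]
  mAB <- (A + B) / 2; mBC <- (B + C) / 2; mCA <- (C + A) / 2
  pts <- rbind((A + mAB + mCA) / 3, (B + mBC + mAB) / 3,
               (C + mCA + mBC) / 3, (mAB + mBC + mCA) / 3)
  e1 <- B - A; e2 <- C - A
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area4 <- rep(sqrt(rowSums(cr^2)) / 8, 4L)   # parent area / 4 per sub-triangle
  loc <- cpp_locate_points(nodes, tets, pts, 1e-9)
  ok <- loc$elem > 0L
  list(elem = loc$elem[ok], bary = loc$bary[ok, , drop = FALSE],
       w = (R / eps) * area4[ok])
}

#' Stabilization reaction band around an immersed valve
#'
#' Per-cell coefficient `(R/eps) * delta_width(d)` where `d` is the distance
#' from the cell centroid to the valve surface.  Passed to [ns_step()]'s
#' `tau_react`, it shrinks the stabilization parameter near the valve; used
#' together with the nodal smoothed-delta quadrature.
#'
#' @inheritParams riis_surface_quadrature
#' @param width band half-width (same units as the mesh).
#' @return per-cell coefficient vector.
#' @export
riis_tau_band <- function(vnodes, vtris, nodes, tets, R, eps, width) {
  cent <- (nodes[tets[, 1L], ] + nodes[tets[, 2L], ] +
           nodes[tets[, 3L], ] + nodes[tets[, 4L], ]) / 4
  d <- cpp_dist_to_surface(cent, vnodes, vtris, 2 * width)
  ifelse(d <= width, (R / eps) * (1 + cos(pi * d / width)) / (2 * width), 0)
}

#' Membrane normals for the projected PSPG stabilization
#'
#' Area-weighted unit normal of the immersed surface per cut fluid cell
#' (zero rows for cells the surface does not cross).  Passing the result as
#' [ns_step()]'s `pspg_proj` projects the pressure-stabilization gradients
#' onto the membrane tangent plane in those cells; a continuous pressure
#' interpolation cannot represent the transvalvular jump, and without the
#' projection the PSPG term acts as an artificial permeability across the
#' closed valve.
#'
#' @inheritParams riis_surface_quadrature
#' @param acc optional M x 3 accumulator from another valve surface.
#' @return M x 3 matrix of (unnormalized) area-weighted normals; normalize
#'   with [normalize_proj()] before use.
#' @export
riis_pspg_projection <- function(vnodes, vtris, nodes, tets, acc = NULL) {
  A <- vnodes[vtris[, 1L], , drop = FALSE]
  B <- vnodes[vtris[, 2L], , drop = FALSE]
  C <- vnodes[vtris[, 3L], , drop = FALSE]
  mAB <- (A + B) / 2; mBC <- (B + C) / 2; mCA <- (C + A) / 2
  pts <- rbind((A + mAB + mCA) / 3, (B + mBC + mAB) / 3,
               (C + mCA + mBC) / 3, (mAB + mBC + mCA) / 3)
  e1 <- B - A; e2 <- C - A
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / 2   # area-weighted normal
  crq <- rbind(cr, cr, cr, cr) / 4
  loc <- cpp_locate_points(nodes, tets, pts, 1e-9)
  ok <- loc$elem > 0L
  out <- if (is.null(acc)) matrix(0, nrow(tets), 3L) else acc
  for (k in 1:3) {
    agg <- rowsum(crq[ok, k], loc$elem[ok])
    ids <- as.integer(rownames(agg))
    out[ids, k] <- out[ids, k] + agg[, 1L]
  }
  out
}

#' @rdname riis_pspg_projection
#' @param proj accumulated normals.
#' @export
normalize_proj <- function(proj) {
  nn <- sqrt(rowSums(proj^2))
  sel <- nn > 0
  proj[sel, ] <- proj[sel, ] / nn[sel]
  proj
}

#' Advance a full systolic simulation on the moving phantom
#'
#' Orchestrates, per time step: elastic mesh motion, ALE and wall
#' velocities, valve advection with the ALE displacement, RIIS delta-field
#' assembly, sigma-model viscosity, the semi-implicit stabilized
#' Navier-Stokes solve, and the aortic valve controller.
#'
#' @param domain a [moving_domain()].
#' @param valves output of [make_scenario_valves()].
#' @param props,les,forcing model parameters.
#' @param dt time step (s); defaults to the domain's.
#' @param t_end final time (s); defaults to the motion interval.
#' @param aortic_state0 initial aortic valve state.
#' @param controller_slices list with `vent` and `aorta` slice definitions
#'   (see [plane_slice()]) for the valve controller, plus `aortic_plane` for
#'   the closure flow rate.
#' @param verbose print per-step diagnostics.
#' @return object of class `flow_history`: arrays of nodal velocity,
#'   pressure, displacement and per-cell subgrid viscosity over time, plus
#'   the controller event log.
#' @export
solve_flow <- function(domain, valves, props = fluid_properties(),
                       les = les_params(), forcing = boundary_forcing(),
                       dt = NULL, t_end = NULL,
                       aortic_state0 = c("closed", "open"),
                       controller_slices = NULL, verbose = FALSE) {
  aortic_state0 <- match.arg(aortic_state0)
  if (is.null(dt)) dt <- domain$dt
  if (is.null(t_end)) t_end <- domain$t_end
  n <- domain$n
  tets <- domain$tets
  delta_les <- if (is.null(les$delta)) domain$mean_edge else les$delta
  ## the smoothed delta layer must be resolvable by the mesh: its half-width
  ## is max(eps, 1.2 x mean shortest edge near the valve) while the penalty
  ## prefactor keeps the physical R/eps (the integral of delta across the
  ## layer is 1, so the physical leak velocity Delta_p eps / R is unchanged)
  local_min_edge <- function(valve) {
    sub <- tets
    e <- function(a, b) sqrt(rowSums((domain$nodes0[sub[, a], , drop = FALSE] -
                                      domain$nodes0[sub[, b], , drop = FALSE])^2))
    minedge <- pmin(e(1, 2), e(1, 3), e(1, 4), e(2, 3), e(2, 4), e(3, 4))
    cent <- (domain$nodes0[sub[, 1L], ] + domain$nodes0[sub[, 2L], ] +
             domain$nodes0[sub[, 3L], ] + domain$nodes0[sub[, 4L], ]) / 4
    dc <- cpp_dist_to_surface(cent, valve$nodes, valve$tris, 0.02)
    sel <- dc < 0.006
    if (!any(sel)) return(domain$mean_edge)
    mean(minedge[sel])
  }
  eps_mv <- max(valves$mitral$eps, 1.2 * local_min_edge(valves$mitral))
  eps_ao <- max(valves$aortic_closed$eps, 1.2 * local_min_edge(valves$aortic_closed))

  ## interpolation of the volume displacement onto valve vertices
  valve_interp <- function(valve) {
    loc <- cpp_locate_points(domain$nodes0, tets, valve$nodes, 1e-8)
    miss <- loc$elem == 0L
    if (any(miss)) {
      ## clamp: nearest node displacement for vertices marginally outside
      nearest <- apply(valve$nodes[miss, , drop = FALSE], 1L, function(p)
        which.min(rowSums(sweep(domain$nodes0, 2L, p)^2)))
    }
    list(loc = loc, miss = miss,
         nearest = if (any(miss)) nearest else integer(0))
  }
  move_valve <- function(valve, itp, dvol) {
    disp <- matrix(0, nrow(valve$nodes), 3L)
    ok <- !itp$miss
    el <- itp$loc$elem[ok]
    bw <- itp$loc$bary[ok, , drop = FALSE]
    for (v in 1:4)
      disp[ok, ] <- disp[ok, ] + bw[, v] * dvol[tets[el, v], , drop = FALSE]
    if (any(itp$miss)) disp[itp$miss, ] <- dvol[itp$nearest, , drop = FALSE]
    valve$nodes + disp
  }
  itp_mitral <- valve_interp(valves$mitral)
  itp_ao_open <- valve_interp(valves$aortic_open)
  itp_ao_closed <- valve_interp(valves$aortic_closed)

  nsteps <- round(t_end / dt)
  times <- seq_len(nsteps) * dt
  wall <- domain$wall
  faces1 <- domain$faces[domain$face_tag == 2L, , drop = FALSE]
  faces2 <- domain$faces[domain$face_tag == 3L, , drop = FALSE]
  bfc <- apply_backflow_control(domain$nodes0, faces1, domain$sig1, forcing$backflow)

  ctrl <- aortic_valve_controller(aortic_state0, t0 = 0)
  refresh_now <- TRUE
  u <- matrix(0, n, 3L)       # null initial condition
  p <- numeric(n)
  d_old <- interp_volume_displacement(domain, 0)
  dmri_old <- interp_displacement(domain, 0)

  U <- array(0, dim = c(nsteps, n, 3L))
  P <- matrix(0, nsteps, n)
  D <- array(0, dim = c(nsteps, n, 3L))
  MU <- matrix(0, nsteps, nrow(tets))
  VSTATE <- character(nsteps)
  mitral_pos <- vector("list", nsteps)

  for (s in seq_len(nsteps)) {
    t_new <- times[s]
    d_new <- interp_volume_displacement(domain, t_new)
    dmri_new <- interp_displacement(domain, t_new)
    vel <- ale_velocities(d_new, d_old, dmri_new, dmri_old, dt, wall = wall)
    nodes_cur <- domain$nodes0 + d_new

    ## valve controller (uses the state at t^n)
    if (!is.null(controller_slices)) {
      pv <- slice_average_pressure(nodes_cur, tets, p, controller_slices$vent)
      pa <- slice_average_pressure(nodes_cur, tets, p, controller_slices$aorta)
      qa <- slice_flux(nodes_cur, tets, u, controller_slices$aortic_plane)
      ctrl <- update_aortic_valve(ctrl, pv, pa, qa, t_new)
    }
    aortic <- if (ctrl$state == "open") valves$aortic_open else valves$aortic_closed
    itp_ao <- if (ctrl$state == "open") itp_ao_open else itp_ao_closed

    mv_nodes <- move_valve(valves$mitral, itp_mitral, d_new)
    ao_nodes <- move_valve(aortic, itp_ao, d_new)
    mitral_pos[[s]] <- mv_nodes
    ## RIIS layer evaluated by surface quadrature (the physical eps is far
    ## below the mesh size, so the smoothed layer collapses onto the surface)
    dd <- distance_and_delta(mv_nodes, valves$mitral$tris, nodes_cur, eps_mv)
    riis <- valves$mitral$R / valves$mitral$eps * dd$delta
    if (ctrl$state == "closed") {
      da <- distance_and_delta(ao_nodes, aortic$tris, nodes_cur, eps_ao)
      riis <- riis + aortic$R / aortic$eps * da$delta
    }
    gd <- (riis[tets[, 1L]] + riis[tets[, 2L]] + riis[tets[, 3L]] +
           riis[tets[, 4L]]) / 4
    if (!is.null(valves$orifice_center)) {
      ## keep the reconstructed regurgitant channel free of the grad-div
      ## boost so it conducts; the orifice region is advected with the valve
      oc <- valves$orifice_center + (mv_nodes[valves$orifice_anchor, ] -
                                     valves$mitral$nodes[valves$orifice_anchor, ])
      cent <- (nodes_cur[tets[, 1L], ] + nodes_cur[tets[, 2L], ] +
               nodes_cur[tets[, 3L], ] + nodes_cur[tets[, 4L], ]) / 4
      near <- rowSums(sweep(cent, 2L, oc)^2) < valves$orifice_radius^2
      gd[near] <- 0
    }

    cg <- cpp_cell_gradients(nodes_cur, tets, u)
    musgs <- musgs_from_sv(cg$sv, les$C, delta_les, props$rho)

    outlets <- list(list(faces = faces1, p_pa = forcing$p1(t_new) * MMHG_TO_PA),
                    list(faces = faces2, p_pa = forcing$p2(t_new) * MMHG_TO_PA))
    res <- ns_step(nodes_cur, tets, u, vel$u_ale, props, dt,
                   musgs_cell = musgs, riis_node = riis, gd_react = gd,
                   wall_nodes = wall,
                   wall_values = vel$u_wall[wall, , drop = FALSE],
                   outlets = outlets, extra_dirichlet = bfc, p_old = p,
                   precond_refresh = refresh_now)
    si <- attr(res, "solver_info")
    ## refresh the preconditioner when the Krylov solve starts to struggle
    refresh_now <- si["fallback"] > 0 || si["iterations"] > 45
    u <- res$u; p <- res$p
    U[s, , ] <- u; P[s, ] <- p; D[s, , ] <- d_new; MU[s, ] <- musgs
    VSTATE[s] <- ctrl$state
    if (verbose)
      message(sprintf("t=%.4f  max|u|=%.3f  aortic=%s  it=%d fb=%d",
                      t_new, max(abs(u)), ctrl$state,
                      as.integer(attr(res, "solver_info")["iterations"]),
                      as.integer(attr(res, "solver_info")["fallback"])))
    d_old <- d_new; dmri_old <- dmri_new
  }
  structure(list(times = times, u = U, p = P, d = D, musgs = MU,
                 valve_state = VSTATE, controller = ctrl,
                 domain = domain, valves = valves, props = props,
                 les = list(C = les$C, delta = delta_les),
                 eps_eff = eps_mv, dt = dt,
                 mitral_pos = mitral_pos),
            class = "flow_history")
}
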