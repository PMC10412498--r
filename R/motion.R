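## ---------------------------------------------------------------------------
## Moving domain: spline interpolation of the imaged boundary displacement in
## time, linear-elastic extension into the volume (the mesh-motion "lifting"
## problem), and the finite-difference ALE / wall velocities.
## All solver-side quantities are in SI units (meters, seconds).
## ---------------------------------------------------------------------------

MMHG_TO_PA <- 133.322

#' Moving computational domain
#'
#' Wraps the phantom geometry (converted to meters) together with the frame
#' displacement fields, the cubic-spline time interpolant, and the
#' linear-elastostatic extension operator with boundary conditions: imposed
#' displacement on the wall, zero displacement on the atrial outlet (kept
#' fixed), zero traction on the aortic outlet (free to follow the rest).
#'
#' The extension is linear in the boundary data, so the volume extensions of
#' the frame fields are precomputed once and interpolated in time.
#'
#' @param geom a `phantom_geometry` (mm).
#' @param motion a `phantom_motion` (frame displacements in mm).
#' @param dt time step (s).
#' @param mu_ext,lambda_ext elastic extension parameters (Pa; defaults 0.4).
#' @return object of class `moving_domain`.
#' @export
moving_domain <- function(geom, motion, dt = 2.5e-4,
                          mu_ext = 0.4, lambda_ext = 0.4) {
  stopifnot(dt > 0)
  nodes0 <- geom$nodes * 1e-3
  frames <- lapply(motion$frames, function(d) d * 1e-3)
  n <- nrow(nodes0)
  wall <- which(geom$node_tag == 1L)
  sig1 <- which(geom$node_tag == 2L)
  sig2 <- which(geom$node_tag == 3L)
  trip <- cpp_asm_elasticity(nodes0, geom$tets, mu_ext, lambda_ext)
  fixed_nodes <- c(wall, sig1)
  fixed <- c(fixed_nodes, fixed_nodes + n, fixed_nodes + 2L * n)
  ndof <- 3L * n
  free <- setdiff(seq_len(ndof), fixed)
  K <- sparseMatrix(i = trip$i + 1L, j = trip$j + 1L, x = trip$x,
                    dims = c(ndof, ndof))
  Kff <- K[free, free, drop = FALSE]
  Kfc <- K[free, fixed, drop = FALSE]
  fact <- Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE)
  dom <- list(geom = geom, nodes0 = nodes0, tets = geom$tets,
              region = geom$region, faces = geom$faces,
              face_tag = geom$face_tag, node_tag = geom$node_tag,
              frames = frames, times = motion$times, dt = dt,
              mu_ext = mu_ext, lambda_ext = lambda_ext,
              wall = wall, sig1 = sig1, sig2 = sig2,
              n = n, fixed = fixed, free = free,
              K = K, Kff_fact = fact, Kfc = Kfc,
              t_end = max(motion$times))
  class(dom) <- "moving_domain"
  ## time-interpolation weights: cubic splines through frame indicators
  dom$weight_funs <- lapply(seq_along(frames), function(i) {
    e <- rep(0, length(frames)); e[i] <- 1
    splinefun(motion$times, e, method = "fmm")
  })
  ## precompute volume extensions of the frame fields
  dom$ext_frames <- lapply(frames, function(d) extend_harmonic(dom, d))
  dom$mean_edge <- mean_edge_length(nodes0, geom$tets)
  dom
}

mean_edge_length <- function(nodes, tets) {
  pairs <- rbind(tets[, c(1L, 2L)], tets[, c(1L, 3L)], tets[, c(1L, 4L)],
                 tets[, c(2L, 3L)], tets[, c(2L, 4L)], tets[, c(3L, 4L)])
  mean(sqrt(rowSums((nodes[pairs[, 1L], ] - nodes[pairs[, 2L], ])^2)))
}

#' Interpolate the boundary displacement in time
#'
#' Componentwise cubic-spline interpolation through the frame fields
#' (classical cubic spline with Forsythe-Malcolm-Moler end conditions, which
#' reproduces cubic polynomials exactly); passes through every frame and is
#' C1 in time.
#'
#' @param domain a `moving_domain`.
#' @param t time in `[0, T_S]` (s).
#' @return N x 3 boundary displacement field (m) at time `t`.
#' @export
interp_displacement <- function(domain, t) {
  if (t < min(domain$times) - 1e-12 || t > max(domain$times) + 1e-12)
    stop("t outside the motion interval [0, T_S]")
  w <- vapply(domain$weight_funs, function(f) f(t), numeric(1))
  out <- matrix(0, domain$n, 3L)
  for (i in seq_along(w))
    if (w[i] != 0) out <- out + w[i] * domain$frames[[i]]
  out
}

## Interpolated *volume* displacement (uses the precomputed frame extensions).
interp_volume_displacement <- function(domain, t) {
  w <- vapply(domain$weight_funs, function(f) f(t), numeric(1))
  out <- matrix(0, domain$n, 3L)
  for (i in seq_along(w))
    if (w[i] != 0) out <- out + w[i] * domain$ext_frames[[i]]
  out
}

#' Elastic extension of a boundary displacement into the volume
#'
#' Solves the linear elastostatic problem
#' `-div(2 mu_EXT grad_s(d) + lambda_EXT div(d) I) = 0` on the reference
#' mesh with `d` prescribed on the wall, `d = 0` on the atrial outlet and
#' zero traction on the aortic outlet.
#'
#' @param domain a `moving_domain`.
#' @param boundary_disp N x 3 field (m); only wall rows are used.
#' @return N x 3 volume displacement (m).
#' @export
extend_harmonic <- function(domain, boundary_disp) {
  n <- domain$n
  if (any(!is.finite(boundary_disp))) stop("non-finite boundary displacement")
  xc <- matrix(0, n, 3L)
  xc[domain$wall, ] <- boundary_disp[domain$wall, , drop = FALSE]
  xc[domain$sig1, ] <- 0
  xfixed <- c(xc[c(domain$wall, domain$sig1), 1L],
              xc[c(domain$wall, domain$sig1), 2L],
              xc[c(domain$wall, domain$sig1), 3L])
  rhs <- -domain$Kfc %*% xfixed
  xf <- as.numeric(Matrix::solve(domain$Kff_fact, rhs))
  d <- numeric(3L * n)
  d[domain$fixed] <- xfixed
  d[domain$free] <- xf
  matrix(d, n, 3L)
}

#' ALE and wall velocities as backward-difference quotients
#'
#' @param d_new,d_old consecutive volume displacement fields (m).
#' @param dmri_new,dmri_old consecutive boundary displacement fields (m).
#' @param dt time step (s).
#' @param wall wall node indices (the wall velocity is zero elsewhere).
#' @return list `u_ale` (N x 3) and `u_wall` (N x 3, nonzero only on wall).
#' @export
ale_velocities <- function(d_new, d_old, dmri_new, dmri_old, dt, wall = NULL) {
  if (dt <= 0) stop("dt must be positive")
  u_ale <- (d_new - d_old) / dt
  u_wall <- (dmri_new - dmri_old) / dt
  if (!is.null(wall)) {
    z <- matrix(0, nrow(u_wall), 3L)
    z[wall, ] <- u_wall[wall, , drop = FALSE]
    u_wall <- z
  }
  list(u_ale = u_ale, u_wall = u_wall)
}
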