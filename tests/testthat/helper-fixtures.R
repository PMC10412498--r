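## Shared fixtures, built once per test session (coarse phantom resolutions
## keep the suite fast; geometry-fidelity checks build their own).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

coarse_mesh_cfg <- function() list(ns = 3L, nr = 2L, n_vent = 6L, n_atr = 6L, n_ao = 5L)

fix_spec <- function() fixture("spec", function()
  phantom_spec(trace_noise_mm = 0, mesh = coarse_mesh_cfg()))

fix_geom <- function() fixture("geom", function() generate_geometry(fix_spec()))

fix_motion <- function() fixture("motion", function()
  generate_motion(fix_spec(), fix_geom()))

fix_traces <- function() fixture("traces", function()
  generate_valve_traces(fix_spec(), fix_geom()))

fix_cloud <- function() fixture("cloud", function()
  fit_rings(assemble_point_cloud(fix_traces())))

## a small straight-pipe mesh with tagged inlet (tag 2) / outlet (tag 3)
pipe_fixture <- function(radius = 5e-3, length = 40e-3, nz = 13L,
                         ns = 3L, nr = 2L, extra_z = NULL) {
  z <- seq(0, length, length.out = nz)
  if (!is.null(extra_z)) z <- sort(unique(c(z, extra_z)))
  m <- cylinder_mesh(radius, z, ns = ns, nr = nr)
  bnd <- mesh_boundary(m$nodes, m$tets)
  fa <- face_normals_areas(m$nodes, bnd$faces)
  tag <- ifelse(fa$normal[, 3] < -0.99, 2L, ifelse(fa$normal[, 3] > 0.99, 3L, 1L))
  rr <- sqrt(m$nodes[, 1]^2 + m$nodes[, 2]^2)
  list(mesh = m, faces = bnd$faces, tag = tag,
       wall_nodes = which(rr > radius - 1e-9),
       radius = radius, length = length)
}

## disc membrane spanning the pipe at z0 (structured polar fan)
disc_membrane <- function(radius, z0, n_ring = 6L, n_az = 24L) {
  th <- (seq_len(n_az) - 1L) / n_az * 2 * pi
  nodes <- rbind(c(0, 0, z0),
                 do.call(rbind, lapply(seq_len(n_ring) / n_ring * radius,
                                       function(r) cbind(r * cos(th), r * sin(th), z0))))
  tris <- cbind(1L, 1L + seq_len(n_az), 1L + c(2:n_az, 1L))
  for (j in seq_len(n_ring - 1L)) {
    i0 <- 1L + (j - 1L) * n_az; i1 <- 1L + j * n_az
    nxt <- c(2:n_az, 1L)
    q <- cbind(i0 + seq_len(n_az), i0 + nxt, i1 + nxt, i1 + seq_len(n_az))
    tris <- rbind(tris, q[, c(1, 2, 3)], q[, c(1, 3, 4)])
  }
  list(nodes = nodes, tris = tris)
}

## steady pressure-driven pipe solve; returns solution + flux helpers
pipe_steady <- function(pf, props, dp_pa, riis_node = NULL, max_iter = 12L) {
  outs <- list(list(faces = pf$faces[pf$tag == 2L, ], p_pa = dp_pa),
               list(faces = pf$faces[pf$tag == 3L, ], p_pa = 0))
  st <- ns_steady(pf$mesh$nodes, pf$mesh$tets, props,
                  wall_nodes = pf$wall_nodes, outlets = outs,
                  riis_node = riis_node, max_iter = max_iter)
  st$flux_out <- boundary_flux(pf$mesh$nodes, st$u, pf$faces[pf$tag == 3L, ])
  st
}
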