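## ---------------------------------------------------------------------------
## Synthetic left-heart phantom: analytic geometry with known ground truth,
## prescribed systolic motion, rendered cine-MRI-like image stacks and
## radial-plane mitral leaflet traces.
##
## Geometry (all lengths mm): the ventricular cavity is the lower half of a
## prolate ellipsoid (semi-axes a, a, c) truncated at the basal plane z = 0.
## The basal disc splits along x = 0 into two mouths: the left half feeds an
## atrial tube that morphs from the half-disc section into circular sections,
## bulges and closes onto a flat outlet (Sigma1); the right half feeds an
## aortic tube with a gentle bend ending at the aortic outlet (Sigma2).
## Cross-sections are star-shaped about the half-disc centroid, so the whole
## cavity has an analytic inside/outside test and quadrature volume oracles.
## ---------------------------------------------------------------------------

#' Phantom specification
#'
#' Parameters of the synthetic left-heart phantom.  The defaults encode the
#' study conditions: a six-frame systole, a target total ejected volume of
#' 92 mL, systole duration 0.32 s, and either a coapting (healthy) valve or a
#' P2 posterior prolapse with a 40 mm^2 regurgitant orifice.
#'
#' @param vent_a,vent_c ventricular semi-axes (mm): short and long.
#' @param target_sv_ml swept cavity-volume change from end diastole to end
#'   systole, before dilation scaling (mL).
#' @param n_frames number of motion frames (end diastole to end systole).
#' @param t_s systole duration (s).
#' @param dilation isotropic dilation factor about the cavity centroid
#'   (1 for the basal geometry, 1.25 for the dilated scenario).
#' @param valve `"healthy"` or `"prolapse"`.
#' @param orifice_area_mm2 regurgitant orifice area (mm^2); must be 0 for a
#'   healthy valve and positive for a prolapse.
#' @param trace_noise_mm isotropic Gaussian noise added to leaflet trace
#'   points (mm), mimicking manual tracing error at 1.25 mm resolution.
#' @param seed integer seed; identical seeds give bit-identical outputs.
#' @param mesh list of mesh density knobs: `ns`, `nr` (butterfly-disc core
#'   half-side cells and radial layers), `n_vent`, `n_atr`, `n_ao`
#'   (extrusion layers per region).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(vent_a = 24, vent_c = 52,
                         target_sv_ml = 92, n_frames = 6L, t_s = 0.32,
                         dilation = 1.0,
                         valve = c("healthy", "prolapse"),
                         orifice_area_mm2 = if (match.arg(valve) == "healthy") 0 else 40,
                         trace_noise_mm = 0.3, seed = 1L,
                         mesh = list()) {
  valve <- match.arg(valve)
  md <- list(ns = 6L, nr = 3L, n_vent = 14L, n_atr = 12L, n_ao = 10L)
  md[names(mesh)] <- mesh
  spec <- list(vent_a = vent_a, vent_c = vent_c,
               atr_h = 1.4 * vent_a, atr_rmax = 0.8 * vent_a,
               atr_rout = 0.5 * vent_a,
               ao_h = 1.7 * vent_a, ao_r = 0.45 * vent_a, ao_bend = 0.2 * vent_a,
               morph_s = 0.35,
               target_sv_ml = target_sv_ml, n_frames = as.integer(n_frames),
               t_s = t_s, dilation = dilation, valve = valve,
               orifice_area_mm2 = orifice_area_mm2,
               trace_noise_mm = trace_noise_mm, seed = as.integer(seed),
               mesh = md)
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(spec$n_frames >= 2L, spec$dilation > 0,
            spec$vent_a > 0, spec$vent_c > 0, spec$t_s > 0)
  if (spec$valve == "healthy" && spec$orifice_area_mm2 != 0)
    stop("a healthy valve must have zero regurgitant orifice area")
  if (spec$valve == "prolapse" && spec$orifice_area_mm2 <= 0)
    stop("a prolapsed valve needs a positive regurgitant orifice area")
  invisible(spec)
}

## Analytic model closure.  All functions work in *reference* (undilated)
## coordinates; `dil` maps reference -> final coordinates about the cavity
## centroid, computed once the mesh exists.
phantom_model <- function(spec) {
  a <- spec$vent_a; cc <- spec$vent_c
  ex <- -4 * a / (3 * pi)          # centroid x of the left half-disc
  r_eq <- a / sqrt(2)              # area-equivalent radius of a half-disc
  smooth01 <- function(s) { s <- pmin(pmax(s, 0), 1); s * s * (3 - 2 * s) }
  w_morph <- function(s) smooth01(s / spec$morph_s)
  ## star-shaped boundary radius of the half-discs about their centroids
  b0_half <- function(theta, side) {
    e <- if (side == "left") ex else -ex
    ct <- cos(theta)
    eu <- e * ct
    t_circ <- -eu + sqrt(pmax(eu^2 + a^2 - e^2, 0))
    t_line <- if (side == "left") ifelse(ct > 1e-12, -e / ct, Inf)
              else                ifelse(ct < -1e-12, -e / ct, Inf)
    pmin(t_circ, t_line)
  }
  bez <- function(s, p0, p1, p2) (1 - s)^2 * p0 + 2 * s * (1 - s) * p1 + s^2 * p2
  r_atr <- function(s) bez(s, r_eq, spec$atr_rmax, spec$atr_rout)
  r_ao  <- function(s) bez(s, r_eq, 0.55 * a, spec$ao_r)
  cx_atr <- function(s) rep(ex, length(s))
  cx_ao  <- function(s) -ex + spec$ao_bend * s^2
  B_tube <- function(s, theta, which) {
    w <- w_morph(s)
    if (which == "atr") (1 - w) * b0_half(theta, "left") + w * r_atr(s)
    else                (1 - w) * b0_half(theta, "right") + w * r_ao(s)
  }
  inside_ref <- function(p) {
    x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
    res <- logical(nrow(p))
    lo <- z <= 0
    res[lo] <- (x[lo]^2 + y[lo]^2) / a^2 + z[lo]^2 / cc^2 <= 1
    up <- !lo
    if (any(up)) {
      xi <- x[up]; yi <- y[up]; zi <- z[up]
      inA <- rep(FALSE, sum(up))
      sA <- zi / spec$atr_h
      okA <- sA <= 1
      if (any(okA)) {
        dx <- xi[okA] - cx_atr(sA[okA]); dy <- yi[okA]
        th <- atan2(dy, dx); r <- sqrt(dx^2 + dy^2)
        inA[okA] <- r <= B_tube(sA[okA], th, "atr")
      }
      inO <- rep(FALSE, sum(up))
      sO <- zi / spec$ao_h
      okO <- sO <= 1
      if (any(okO)) {
        dx <- xi[okO] - cx_ao(sO[okO]); dy <- yi[okO]
        th <- atan2(dy, dx); r <- sqrt(dx^2 + dy^2)
        inO[okO] <- r <= B_tube(sO[okO], th, "ao")
      }
      res[up] <- inA | inO
    }
    res
  }
  list(a = a, c = cc, ex = ex, r_eq = r_eq,
       w_morph = w_morph, b0_half = b0_half,
       r_atr = r_atr, r_ao = r_ao, cx_atr = cx_atr, cx_ao = cx_ao,
       B_tube = B_tube, inside_ref = inside_ref, smooth01 = smooth01)
}

#' Analytic cavity volume of the phantom
#'
#' Ventricular half-ellipsoid in closed form plus the two tube volumes by
#' fine quadrature of the analytic cross-section areas.  Independent of any
#' mesh; used as an oracle for the discrete cavity volume.
#'
#' @param spec a [phantom_spec()].
#' @param part `"total"`, `"ventricle"`, `"atrium"` or `"aorta"`.
#' @param n_quad quadrature resolution.
#' @return volume in mm^3 (including the dilation factor).
#' @export
phantom_cavity_volume <- function(spec, part = c("total", "ventricle", "atrium", "aorta"),
                                  n_quad = 400L) {
  part <- match.arg(part)
  mod <- phantom_model(spec)
  vent <- 2 / 3 * pi * mod$a^2 * mod$c
  tube_vol <- function(which, h) {
    th <- seq(0, 2 * pi, length.out = 1441L)[-1441L]
    s <- (seq_len(n_quad) - 0.5) / n_quad
    A <- vapply(s, function(ss) {
      b <- mod$B_tube(ss, th, which)
      0.5 * mean(b^2) * 2 * pi
    }, numeric(1))
    mean(A) * h
  }
  v <- switch(part,
    ventricle = vent,
    atrium = tube_vol("atr", spec$atr_h),
    aorta = tube_vol("ao", spec$ao_h),
    total = vent + tube_vol("atr", spec$atr_h) + tube_vol("ao", spec$ao_h))
  v * spec$dilation^3
}

#' Generate the phantom geometry
#'
#' Builds the tagged tetrahedral volume mesh of the left-heart cavity
#' (ventricle + atrium + aorta), its oriented boundary with tags
#' (wall, atrial outlet Sigma1, aortic outlet Sigma2), and attaches the
#' analytic model used by the image renderer and the motion generator.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_geometry` with elements `nodes` (mm),
#'   `tets`, `region` (1 ventricle, 2 atrium, 3 aorta), `faces`, `face_tag`
#'   (1 wall, 2 Sigma1, 3 Sigma2), `node_tag`, `model`, `spec`, `center`
#'   (dilation center, mm).
#' @export
generate_geometry <- function(spec) {
  validate_phantom_spec(spec)
  mod <- phantom_model(spec)
  md <- spec$mesh
  d <- disc_butterfly(md$ns, md$nr)
  nd <- nrow(d$xy)
  a <- mod$a

  ## --- ventricle: base disc at z = 0 extruded down the ellipsoid ----------
  phi_max <- asin(0.93)
  phis <- seq(0, phi_max, length.out = md$n_vent + 1L)
  vent_layers <- lapply(phis, function(ph)
    cbind(d$xy * (a * cos(ph)), -mod$c * sin(ph)))
  nodes <- do.call(rbind, vent_layers)
  apex <- c(0, 0, -mod$c)
  apex_id <- nrow(nodes) + 1L
  nodes <- rbind(nodes, apex)
  layer_ids <- lapply(seq_along(vent_layers), function(k) (k - 1L) * nd + seq_len(nd))

  tet_list <- list()
  reg_list <- list()
  for (k in seq_len(length(vent_layers) - 1L)) {
    ## stack downward: top layer k, bottom layer k+1
    b <- matrix(layer_ids[[k + 1L]][d$tris], ncol = 3L)
    t <- matrix(layer_ids[[k]][d$tris], ncol = 3L)
    tet_list[[length(tet_list) + 1L]] <- split_prisms(b, t)
    reg_list[[length(reg_list) + 1L]] <- 1L
  }
  last <- layer_ids[[length(layer_ids)]]
  cap <- cbind(matrix(last[d$tris], ncol = 3L), apex_id)
  tet_list[[length(tet_list) + 1L]] <- cap
  reg_list[[length(reg_list) + 1L]] <- 1L

  ## --- tubes ----------------------------------------------------------------
  ## z-layer refinement band (finer axial spacing where an immersed valve
  ## sits, mirroring the local mesh refinement close to the valves)
  refine_s <- function(nlay, s0, half, factor) {
    s <- seq(0, 1, length.out = nlay + 1L)
    ds <- 1 / nlay
    fine <- seq(max(0, s0 - half), min(1, s0 + half), by = ds * factor)
    sort(unique(round(c(s, fine), 10)))
  }

  tube_layers <- function(which, nlay, h) {
    side <- if (which == "atr") "left" else "right"
    keep_tri <- if (which == "atr") {
      cent <- (d$xy[d$tris[, 1L], 1L] + d$xy[d$tris[, 2L], 1L] + d$xy[d$tris[, 3L], 1L]) / 3
      d$tris[cent < 0, , drop = FALSE]
    } else {
      cent <- (d$xy[d$tris[, 1L], 1L] + d$xy[d$tris[, 2L], 1L] + d$xy[d$tris[, 3L], 1L]) / 3
      d$tris[cent > 0, , drop = FALSE]
    }
    sub_nodes <- sort(unique(as.integer(keep_tri)))
    tri_local <- matrix(match(keep_tri, sub_nodes), ncol = 3L)
    e0 <- if (which == "atr") mod$ex else -mod$ex
    p0 <- d$xy[sub_nodes, , drop = FALSE] * a
    dx <- p0[, 1L] - e0; dy <- p0[, 2L]
    th <- atan2(dy, dx)
    rho <- sqrt(dx^2 + dy^2)
    b0 <- mod$b0_half(th, side)
    rho_hat <- ifelse(rho < 1e-9, 0, rho / b0)
    s_vals <- if (which == "atr") refine_s(nlay, 0.45, 0.16, 0.25)
              else refine_s(nlay, 0.35, 0.14, 0.5)
    lays <- lapply(s_vals, function(s) {
      Bv <- mod$B_tube(s, th, which)
      cx <- if (which == "atr") mod$cx_atr(s) else mod$cx_ao(s)
      cbind(cx + rho_hat * Bv * cos(th), rho_hat * Bv * sin(th), s * h)
    })
    list(sub = sub_nodes, tri = tri_local, layers = lays)
  }

  add_tube <- function(tb, region_code) {
    nl <- length(tb$layers)
    nsub <- length(tb$sub)
    ## layer 1 (s=0) coincides with the base disc nodes
    new_nodes <- do.call(rbind, tb$layers[-1L])
    off <- nrow(nodes)
    nodes <<- rbind(nodes, new_nodes)
    ids <- vector("list", nl)
    ids[[1L]] <- tb$sub              # base disc global ids (layer 1 of ventricle stack)
    for (k in 2:nl) ids[[k]] <- off + (k - 2L) * nsub + seq_len(nsub)
    for (k in seq_len(nl - 1L)) {
      b <- matrix(ids[[k]][tb$tri], ncol = 3L)
      t <- matrix(ids[[k + 1L]][tb$tri], ncol = 3L)
      tet_list[[length(tet_list) + 1L]] <<- split_prisms(b, t)
      reg_list[[length(reg_list) + 1L]] <<- region_code
    }
    ids[[nl]]
  }

  atr <- tube_layers("atr", md$n_atr, spec$atr_h)
  top_atr <- add_tube(atr, 2L)
  ao <- tube_layers("ao", md$n_ao, spec$ao_h)
  top_ao <- add_tube(ao, 3L)

  region <- rep.int(unlist(reg_list), vapply(tet_list, nrow, 1L))
  tets <- do.call(rbind, tet_list)
  tets <- orient_tets(nodes, tets)
  vol <- tet_volumes(nodes, tets)
  if (any(vol <= 0)) stop("phantom mesh assembly produced degenerate cells")

  ## dilation about the cavity centroid
  cent <- colSums(nodes[tets[, 1L], ] + nodes[tets[, 2L], ] +
                  nodes[tets[, 3L], ] + nodes[tets[, 4L], ]) / (4 * nrow(tets))
  ## volume-weighted centroid
  cw <- (nodes[tets[, 1L], ] + nodes[tets[, 2L], ] + nodes[tets[, 3L], ] + nodes[tets[, 4L], ]) / 4
  cent <- colSums(cw * vol) / sum(vol)
  if (spec$dilation != 1.0)
    nodes <- sweep(sweep(nodes, 2L, cent, "-") * spec$dilation, 2L, cent, "+")

  bnd <- mesh_boundary(nodes, tets)
  check_closed_surface(bnd$faces)
  face_tag <- rep(1L, nrow(bnd$faces))
  in_set <- function(f, set) {
    m <- matrix(f %in% set, ncol = 3L)
    rowSums(m) == 3L
  }
  face_tag[in_set(bnd$faces, top_atr)] <- 2L
  face_tag[in_set(bnd$faces, top_ao)] <- 3L
  ## node tags: outlet interiors are 2/3; every node on a wall face is wall
  ## (outlet rims are no-slip, like the wall they belong to)
  node_tag <- integer(nrow(nodes))
  node_tag[unique(as.integer(bnd$faces[face_tag == 2L, ]))] <- 2L
  node_tag[unique(as.integer(bnd$faces[face_tag == 3L, ]))] <- 3L
  node_tag[unique(as.integer(bnd$faces[face_tag == 1L, ]))] <- 1L

  out <- list(nodes = nodes, tets = tets, region = region,
              faces = bnd$faces, face_owner = bnd$owner, face_tag = face_tag,
              node_tag = node_tag, model = mod, spec = spec, center = cent,
              base_ids = layer_ids[[1L]], apex_id = apex_id)
  class(out) <- "phantom_geometry"
  out
}

check_closed_surface <- function(faces) {
  ed <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3L, 1L)])
  key <- paste(pmin(ed[, 1L], ed[, 2L]), pmax(ed[, 1L], ed[, 2L]))
  cnt <- table(key)
  if (any(cnt != 2L))
    stop("boundary surface is not closed (non-watertight assembly)")
  invisible(TRUE)
}

#' Cavity volume of a (possibly displaced) phantom mesh
#'
#' Divergence-theorem volume of the boundary surface after adding a nodal
#' displacement field.
#'
#' @param geom a [generate_geometry()] result.
#' @param displacement N x 3 nodal displacement (mm), or NULL.
#' @return volume in mm^3.
#' @export
cavity_volume <- function(geom, displacement = NULL) {
  nodes <- geom$nodes
  if (!is.null(displacement)) nodes <- nodes + displacement
  surface_enclosed_volume(nodes, geom$faces)
}

## Map final (dilated) coordinates to reference coordinates.
to_reference <- function(geom, p) {
  f <- geom$spec$dilation
  if (f == 1.0) return(p)
  sweep(sweep(p, 2L, geom$center, "-") / f, 2L, geom$center, "+")
}
from_reference <- function(geom, p) {
  f <- geom$spec$dilation
  if (f == 1.0) return(p)
  sweep(sweep(p, 2L, geom$center, "-") * f, 2L, geom$center, "+")
}

## Analytic systolic contraction field (reference coords, unit amplitude):
## radial contraction of the ventricle with longitudinal shortening, blended
## to zero up the tubes.  Returned as the *end-diastolic* displacement shape;
## frame displacements are gamma_i * alpha * shape.
motion_shape <- function(geom, p_ref) {
  spec <- geom$spec
  mod <- geom$model
  zb <- 0.5 * spec$atr_h
  z <- p_ref[, 3L]
  chi <- ifelse(z <= 0, 1, {
    s <- pmin(z / zb, 1); (1 - s)^2 * (1 + 2 * s)
  })
  kappa <- 0.6
  cbind(chi * p_ref[, 1L], chi * p_ref[, 2L],
        ifelse(z < 0, kappa * z, 0) * chi)
}

#' Generate the prescribed systolic boundary motion
#'
#' Frame displacement fields referenced to the end-systolic configuration
#' (the mesh itself): frame `n_frames` has zero displacement, frame 1 is end
#' diastole.  The contraction amplitude is solved by 1-D root finding so the
#' swept cavity-volume change matches the target stroke volume (scaled by
#' the dilation cubed, since the dilated scenario dilates the displacement
#' field as well).
#'
#' @param spec a [phantom_spec()].
#' @param geom matching [generate_geometry()] output (built if omitted).
#' @return object of class `phantom_motion`: `frames` (list of N x 3 mm
#'   displacement fields), `times` (s), `alpha`, `volumes` (mm^3 per frame).
#' @export
generate_motion <- function(spec, geom = generate_geometry(spec)) {
  p_ref <- to_reference(geom, geom$nodes)
  shape <- motion_shape(geom, p_ref) * spec$dilation  # dilate the field too
  v_es <- cavity_volume(geom)
  sv_target <- spec$target_sv_ml * 1000 * spec$dilation^3  # mm^3
  f <- function(alpha) cavity_volume(geom, alpha * shape) - v_es - sv_target
  if (f(1.0) < 0) stop("target stroke volume unreachable with unit-amplitude contraction")
  alpha <- uniroot(f, c(0, 1.0), tol = 1e-10)$root
  nfr <- spec$n_frames
  tt <- seq(0, spec$t_s, length.out = nfr)
  gam <- (1 + cos(pi * tt / spec$t_s)) / 2
  frames <- lapply(gam, function(g) g * alpha * shape)
  vols <- vapply(frames, function(d) cavity_volume(geom, d), numeric(1))
  ## deformed-mesh validity at end diastole
  if (any(tet_volumes(geom$nodes + frames[[1L]], geom$tets) <= 0))
    stop("deformed phantom surface self-intersects at end diastole")
  out <- list(frames = frames, times = tt, alpha = alpha, volumes = vols,
              shape = shape)
  class(out) <- "phantom_motion"
  out
}

## Deformation map at motion fraction gamma (final coords):
##   Phi(x) = x + gamma * alpha * dilation * shape(to_ref(x))
## and its approximate inverse by fixed-point iteration.
phantom_inverse_map <- function(geom, motion, gamma, pts, iters = 8L) {
  x <- pts
  for (k in seq_len(iters)) {
    d <- gamma * motion$alpha * geom$spec$dilation *
         motion_shape(geom, to_reference(geom, x))
    x <- pts - d
  }
  x
}

#' Render cine-MRI-like image stacks of the moving phantom
#'
#' Voxel values are the partial-volume fraction of the cavity interior,
#' averaged through the slice thickness (by sub-sampling) and over the
#' in-plane voxel footprint.  The default plan mimics a short-axis stack of
#' 15 slices with 8 mm thickness/spacing and 1 mm in-plane resolution plus
#' two long-axis single slices on orthogonal planes through the long axis.
#'
#' @param spec,geom,motion phantom spec, geometry and motion.
#' @param slice_plan optional list overriding `sax_spacing_mm` (8),
#'   `sax_n` (15), `inplane_mm` (1), `subsamp` (c(2,2,5): in-plane x 2 and
#'   through-thickness samples), `noise_sd` (0), `frames` (indices).
#' @return list with `sax` (a `voxel_series`) and `lax` (list of two
#'   `voxel_series`).
#' @export
render_image_series <- function(spec, geom = generate_geometry(spec),
                                motion = generate_motion(spec, geom),
                                slice_plan = list()) {
  sp <- list(sax_spacing_mm = 8, sax_n = 15L, inplane_mm = 1,
             subsamp = c(2L, 2L, 5L), noise_sd = 0,
             frames = seq_len(spec$n_frames), thickness_mm = 8)
  sp[names(slice_plan)] <- slice_plan
  f <- spec$dilation
  a <- geom$model$a * f
  ## spatial extents (final coords): motion only shrinks the ED -> ES cavity,
  ## so the ED configuration bounds everything.
  ed <- geom$nodes + motion$frames[[1L]]
  lim <- apply(ed, 2L, range)
  margin <- 4
  zlo <- lim[1L, 3L] - 2
  z_slices <- zlo + (seq_len(sp$sax_n) - 1L) * sp$sax_spacing_mm
  if (max(z_slices) < lim[1L, 3L]) stop("slice plan lies outside the phantom bounding box")
  xg <- seq(lim[1L, 1L] - margin, lim[2L, 1L] + margin, by = sp$inplane_mm)
  yg <- seq(lim[1L, 2L] - margin, lim[2L, 2L] + margin, by = sp$inplane_mm)

  gammas <- (1 + cos(pi * motion$times / spec$t_s)) / 2
  value_at <- function(pts, gamma) {
    x <- phantom_inverse_map(geom, motion, gamma, pts)
    as.numeric(geom$model$inside_ref(to_reference(geom, x)))
  }
  ## averaged indicator over voxel footprint
  sample_offsets <- function(n, h) (seq_len(n) - (n + 1) / 2) / n * h
  voxel_values <- function(centers, gamma, inplane_axes, thick_axis) {
    offs <- expand.grid(a1 = sample_offsets(sp$subsamp[1L], sp$inplane_mm),
                        a2 = sample_offsets(sp$subsamp[2L], sp$inplane_mm),
                        a3 = sample_offsets(sp$subsamp[3L], sp$thickness_mm))
    acc <- numeric(nrow(centers))
    for (k in seq_len(nrow(offs))) {
      pts <- centers + matrix(offs$a1[k] * inplane_axes[, 1L], nrow(centers), 3L, byrow = TRUE) +
                       matrix(offs$a2[k] * inplane_axes[, 2L], nrow(centers), 3L, byrow = TRUE) +
                       matrix(offs$a3[k] * thick_axis, nrow(centers), 3L, byrow = TRUE)
      acc <- acc + value_at(pts, gamma)
    }
    acc / nrow(offs)
  }

  grid2 <- as.matrix(expand.grid(x = xg, y = yg))
  sax_frames <- lapply(sp$frames, function(i) {
    arr <- array(0, dim = c(length(xg), length(yg), length(z_slices)))
    for (k in seq_along(z_slices)) {
      centers <- cbind(grid2, z_slices[k])
      v <- voxel_values(centers, gammas[i], diag(3)[, 1:2], c(0, 0, 1))
      if (sp$noise_sd > 0) v <- v + rnorm(length(v), 0, sp$noise_sd)
      arr[, , k] <- matrix(v, length(xg), length(yg))
    }
    arr
  })
  sax <- voxel_series(sax_frames,
                      spacing = c(sp$inplane_mm, sp$inplane_mm, sp$sax_spacing_mm),
                      origin = c(xg[1L], yg[1L], z_slices[1L]),
                      axes = diag(3), times = motion$times[sp$frames])

  ## two long-axis single slices: planes y = 0 and x = 0
  zg <- seq(lim[1L, 3L] - margin, lim[2L, 3L] + margin, by = sp$inplane_mm)
  lax_one <- function(e1, e2, nrm) {
    g1 <- seq(min(lim[, 1:2]) - margin, max(lim[, 1:2]) + margin, by = sp$inplane_mm)
    grid <- as.matrix(expand.grid(u = g1, v = zg))
    frames <- lapply(sp$frames, function(i) {
      centers <- grid[, 1L] %o% e1 + grid[, 2L] %o% e2
      v <- voxel_values(centers, gammas[i], cbind(e1, e2), nrm)
      if (sp$noise_sd > 0) v <- v + rnorm(length(v), 0, sp$noise_sd)
      array(matrix(v, length(g1), length(zg)), dim = c(length(g1), length(zg), 1L))
    })
    voxel_series(frames, spacing = c(sp$inplane_mm, sp$inplane_mm, sp$thickness_mm),
                 origin = c(g1[1L] * e1 + zg[1L] * e2),
                 axes = cbind(e1, e2, nrm), times = motion$times[sp$frames])
  }
  lax <- list(lax_one(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0)),
              lax_one(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)))
  list(sax = sax, lax = lax)
}

#' Time-resolved voxel image series
#'
#' Container for anisotropic scalar image stacks: a list of 3-D arrays (one
#' per frame, shared grid), per-axis spacing (mm), a world-space origin (the
#' center of voxel \[1,1,1\]) and orthonormal grid axes (columns).
#'
#' @param frames list of 3-D arrays of identical dimension.
#' @param spacing positive length-3 spacing (mm).
#' @param origin world coordinates of the first voxel center.
#' @param axes 3 x 3 orthonormal matrix, columns = grid directions.
#' @param times frame times (s).
#' @return object of class `voxel_series`.
#' @export
voxel_series <- function(frames, spacing, origin, axes = diag(3), times = NULL) {
  stopifnot(all(spacing > 0), length(spacing) == 3L)
  dims <- lapply(frames, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("all frames of a voxel series must share grid dimensions")
  structure(list(frames = frames, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), axes = axes,
                 times = times, dim = dims[[1L]]),
            class = "voxel_series")
}

#' Write a voxel series frame as NIfTI
#' @param vs a `voxel_series`.
#' @param path output file (`.nii`); one file per frame with suffixes if
#'   several frames.
#' @param frame frame index (default all).
#' @export
write_voxel_nifti <- function(vs, path, frame = NULL) {
  idx <- if (is.null(frame)) seq_along(vs$frames) else frame
  outs <- character(0)
  for (i in idx) {
    p <- if (length(idx) > 1L)
      sub("\\.nii(\\.gz)?$", sprintf("_f%02d.nii", i), path) else path
    img <- RNifti::asNifti(vs$frames[[i]])
    RNifti::pixdim(img) <- vs$spacing
    RNifti::writeNifti(img, p)
    outs <- c(outs, p)
  }
  invisible(outs)
}

#' Read a NIfTI file into a single-frame voxel series
#' @param path NIfTI file.
#' @param origin,axes,time optional world geometry (NIfTI qform is ignored;
#'   the phantom pipeline carries geometry explicitly).
#' @export
read_voxel_nifti <- function(path, origin = c(0, 0, 0), axes = diag(3), time = 0) {
  img <- RNifti::readNifti(path)
  sp <- attr(img, "pixdim")[1:3]
  voxel_series(list(array(as.numeric(img), dim = dim(img))), spacing = sp,
               origin = origin, axes = axes, times = time)
}

## ---------------------------------------------------------------------------
## Mitral valve traces
## ---------------------------------------------------------------------------

## Analytic leaflet model in annulus-local coordinates.  The annulus is a
## circle of radius r_ann in the plane zeta = 0; the closure (coaptation)
## arc runs through the posterior half (azimuth psi in (90, 270) deg),
## dipping toward the ventricle.  Anterior profiles run from the anterior
## annulus across the orifice center to the arc; posterior profiles run
## inward from the posterior annulus.  A P2 prolapse displaces the posterior
## free margin toward the atrium over the mid-posterior sector.
valve_shape <- function(r_ann, prolapse_bump = 0, sector_deg = 45) {
  rho0 <- 0.35 * r_ann
  depth <- 0.45 * r_ann
  sag_a <- 0.10 * r_ann
  sag_p <- 0.05 * r_ann
  arc <- function(psi) {   # psi in radians, in (pi/2, 3*pi/2)
    srel <- sin(psi - pi / 2)
    list(rho = r_ann - (r_ann - rho0) * srel, zeta = -depth * srel)
  }
  bump_w <- function(psi) {
    dpsi <- (psi - pi) * 180 / pi
    ifelse(abs(dpsi) < sector_deg, cos(pi / 2 * dpsi / sector_deg)^2, 0)
  }
  q <- (seq_len(32L) - 1L) / 31
  anterior <- function(phi) {  # phi in (-pi/2, pi/2): anterior azimuth
    psi <- phi + pi
    A <- arc(psi)
    t <- (1 - q) * r_ann + q * (-A$rho)
    zeta <- q * A$zeta - sag_a * sin(pi * q)
    cbind(t * cos(phi), t * sin(phi), zeta)
  }
  posterior <- function(phi) { # same plane; profile starts at azimuth phi+pi
    psi <- phi + pi
    A <- arc(psi)
    t <- -((1 - q) * r_ann + q * A$rho)
    zeta <- q * A$zeta - sag_p * sin(pi * q)
    base <- cbind(t * cos(phi), t * sin(phi), zeta)
    if (prolapse_bump > 0) {
      ## flail-like eversion: the P2 segment swings toward the atrium as a
      ## whole (full displacement from mid-profile on), leaving a channel as
      ## wide as the margin gap rather than a hinge-pinched slit
      qw <- pmin(pmax(q / 0.5, 0), 1)
      qw <- qw * qw * (3 - 2 * qw)
      w <- bump_w(psi) * prolapse_bump * qw
      er <- c(cos(psi), sin(psi), 0)
      dirv <- (c(0, 0, 1) + 0.35 * er)
      base <- base + (w %o% dirv)
    }
    base
  }
  margin_gap_area <- function(n = 721L) {
    psis <- seq(pi / 2, 3 * pi / 2, length.out = n)
    Aa <- arc(psis)
    Ma <- cbind(Aa$rho * cos(psis), Aa$rho * sin(psis), Aa$zeta)
    wb <- bump_w(psis) * prolapse_bump
    er <- cbind(cos(psis), sin(psis), 0)
    Mp <- Ma + wb * cbind(0.35 * er[, 1L], 0.35 * er[, 2L], 1)
    ## strip area between the two margin curves
    area <- 0
    for (i in seq_len(n - 1L)) {
      t1 <- 0.5 * sqrt(sum(cross3(Mp[i, ] - Ma[i, ], Ma[i + 1L, ] - Ma[i, ])^2))
      t2 <- 0.5 * sqrt(sum(cross3(Mp[i + 1L, ] - Mp[i, ], Ma[i + 1L, ] - Mp[i, ])^2))
      area <- area + t1 + t2
    }
    area
  }
  list(anterior = anterior, posterior = posterior, arc = arc,
       margin_gap_area = margin_gap_area, q = q,
       r_ann = r_ann, rho0 = rho0, depth = depth)
}

cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                           u[3] * v[1] - u[1] * v[3],
                           u[1] * v[2] - u[2] * v[1])

#' Generate radial-plane mitral leaflet traces
#'
#' Emulates the radial cine-MRI tracing protocol: 18 planes through the
#' annulus center rotated 10 degrees apart; on each plane an anterior and a
#' posterior leaflet profile of 32 points from the annulus to the free
#' margin.  For a healthy valve the last anterior and posterior points of
#' each plane coincide exactly (full coaptation); for a P2 prolapse the
#' posterior free margin of the mid-posterior sector is displaced toward the
#' atrium, opening a regurgitant orifice of the requested area (solved by
#' root finding on the analytic margin-gap area).
#'
#' @param spec a [phantom_spec()].
#' @param geom matching geometry (for the annulus placement).
#' @return object of class `valve_traces`: `planes` (list with `alpha_deg`,
#'   `anterior`, `posterior` 32 x 3 matrices, mm, world coordinates),
#'   `center`, `axis`, `r_ann`, `orifice_area_mm2`, `bump`.
#' @export
generate_valve_traces <- function(spec, geom = generate_geometry(spec)) {
  mod <- geom$model
  s_mv <- 0.45
  r_tube <- mod$r_atr(s_mv)
  r_ann <- 0.92 * r_tube
  center_ref <- c(mod$cx_atr(s_mv), 0, s_mv * spec$atr_h)
  bump <- 0
  if (spec$valve == "prolapse") {
    sh0 <- valve_shape(r_ann)
    ## orifice area is specified for the undilated valve; dilation scales it
    ## by dilation^2 (the dilated scenario dilates the valve with the rest)
    f <- function(b) valve_shape(r_ann, prolapse_bump = b)$margin_gap_area() -
      spec$orifice_area_mm2
    bmax <- 0.8 * r_ann
    if (f(bmax) < 0)
      stop("requested regurgitant orifice area is incompatible with the leaflet dimensions")
    bump <- uniroot(f, c(0, bmax), tol = 1e-9)$root
  }
  sh <- valve_shape(r_ann, prolapse_bump = bump)
  alphas <- (seq_len(18L) - 1L) * 10
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(spec$seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  planes <- lapply(alphas, function(al) {
    ## anterior half-azimuth of this plane: the one in [-90, 90)
    phi <- al * pi / 180
    if (phi >= pi / 2) phi <- phi - pi
    ant <- sh$anterior(phi)
    pos <- sh$posterior(phi)
    if (spec$trace_noise_mm > 0) {
      ant <- ant + matrix(rnorm(96, 0, spec$trace_noise_mm), 32L, 3L)
      pos <- pos + matrix(rnorm(96, 0, spec$trace_noise_mm), 32L, 3L)
    }
    if (spec$valve == "healthy") pos[32L, ] <- ant[32L, ]  # coaptation is exact
    to_world <- function(m) from_reference(geom, sweep(m, 2L, center_ref, "+"))
    list(alpha_deg = al,
         normal = c(-sin(phi), cos(phi), 0),
         anterior = to_world(ant), posterior = to_world(pos))
  })
  out <- list(planes = planes,
              center = from_reference(geom, matrix(center_ref, 1L))[1L, ],
              axis = c(0, 0, 1),
              r_ann = r_ann * spec$dilation,
              orifice_area_mm2 = spec$orifice_area_mm2 * spec$dilation^2,
              bump = bump * spec$dilation, valve = spec$valve)
  class(out) <- "valve_traces"
  out
}

#' Write / read valve traces as CSV
#'
#' Columns: plane_id, leaflet, sample_idx, x, y, z (mm).
#' @param traces a `valve_traces` object.
#' @param path CSV file.
#' @export
write_traces_csv <- function(traces, path) {
  rows <- do.call(rbind, lapply(seq_along(traces$planes), function(k) {
    pl <- traces$planes[[k]]
    rbind(data.frame(plane_id = k, leaflet = "anterior", sample_idx = 1:32,
                     x = pl$anterior[, 1], y = pl$anterior[, 2], z = pl$anterior[, 3]),
          data.frame(plane_id = k, leaflet = "posterior", sample_idx = 1:32,
                     x = pl$posterior[, 1], y = pl$posterior[, 2], z = pl$posterior[, 3]))
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @param center,axis annulus center and axis to attach to the re-read traces.
#' @export
read_traces_csv <- function(path, center = NULL, axis = c(0, 0, 1)) {
  df <- read.csv(path)
  ids <- sort(unique(df$plane_id))
  planes <- lapply(ids, function(k) {
    sub <- df[df$plane_id == k, ]
    ant <- as.matrix(sub[sub$leaflet == "anterior", c("x", "y", "z")])[order(sub$sample_idx[sub$leaflet == "anterior"]), ]
    pos <- as.matrix(sub[sub$leaflet == "posterior", c("x", "y", "z")])[order(sub$sample_idx[sub$leaflet == "posterior"]), ]
    list(alpha_deg = (k - 1) * 10, anterior = ant, posterior = pos)
  })
  if (is.null(center))
    center <- colMeans(do.call(rbind, lapply(planes, function(p) p$anterior[1L, , drop = FALSE])))
  structure(list(planes = planes, center = center, axis = axis),
            class = "valve_traces")
}
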