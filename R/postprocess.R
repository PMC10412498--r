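## ---------------------------------------------------------------------------
## Hemodynamic postprocessing: planar cross-sections (marching tetrahedra),
## slice flow rates and pressures, valve timing, clinical indices
## (SV/CO/RV/RF), velocity maxima, atrial turbulence ratio, wall shear
## stress fields and summaries.
## ---------------------------------------------------------------------------

#' Planar slice definition
#'
#' @param origin point on the plane.
#' @param normal plane normal (normalized internally); flow in the normal
#'   direction counts positive.
#' @param rmax only mesh cells whose centroid lies within `rmax` of
#'   `origin` are cut (restricts the section to one vessel).
#' @param region optional region code(s) to restrict the cut.
#' @param name label.
#' @export
plane_slice <- function(origin, normal, rmax = Inf, region = NULL, name = "slice") {
  normal <- normal / sqrt(sum(normal^2))
  structure(list(origin = origin, normal = normal, rmax = rmax,
                 region = region, name = name), class = "plane_slice")
}

## Cut a tet mesh with a plane; returns interpolation data for the polygon
## vertices: rows (i1, i2, w) meaning point = (1-w) x_i1 + w x_i2, plus a
## triangle list into those points.
slice_cut <- function(nodes, tets, slice, region_tags = NULL) {
  o <- slice$origin; nn <- slice$normal
  s <- as.numeric(sweep(nodes, 2L, o, "-") %*% nn)
  scale <- max(abs(s), 1e-12)
  s[s == 0] <- 1e-12 * scale
  s1 <- s[tets[, 1L]]; s2 <- s[tets[, 2L]]; s3 <- s[tets[, 3L]]; s4c <- s[tets[, 4L]]
  cand <- which(pmin(s1, s2, s3, s4c) < 0 & pmax(s1, s2, s3, s4c) > 0)
  if (!is.null(slice$region) && !is.null(region_tags))
    cand <- cand[region_tags[cand] %in% slice$region]
  if (is.finite(slice$rmax) && length(cand)) {
    cent <- (nodes[tets[cand, 1L], , drop = FALSE] + nodes[tets[cand, 2L], , drop = FALSE] +
             nodes[tets[cand, 3L], , drop = FALSE] + nodes[tets[cand, 4L], , drop = FALSE]) / 4
    cand <- cand[sqrt(rowSums(sweep(cent, 2L, o, "-")^2)) <= slice$rmax]
  }
  if (!length(cand))
    stop(sprintf("slice '%s' does not intersect the mesh", slice$name))
  edges <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L), c(3L, 4L))
  ip1 <- integer(0); ip2 <- integer(0); ww <- numeric(0)
  tri <- matrix(0L, 0L, 3L); tet_of <- integer(0)
  npts <- 0L
  for (e in cand) {
    vid <- tets[e, ]
    se <- s[vid]
    neg <- which(se < 0)
    pts <- integer(0)
    add_pt <- function(a, b) {
      t <- se[a] / (se[a] - se[b])
      ip1 <<- c(ip1, vid[a]); ip2 <<- c(ip2, vid[b]); ww <<- c(ww, t)
      npts <<- npts + 1L
      npts
    }
    if (length(neg) == 1L || length(neg) == 3L) {
      lone <- if (length(neg) == 1L) neg else setdiff(1:4, neg)
      others <- setdiff(1:4, lone)
      pts <- vapply(others, function(b) add_pt(lone, b), integer(1))
      tri <- rbind(tri, pts)
      tet_of <- c(tet_of, e)
    } else {
      a <- neg; b <- setdiff(1:4, neg)
      p11 <- add_pt(a[1L], b[1L]); p12 <- add_pt(a[1L], b[2L])
      p22 <- add_pt(a[2L], b[2L]); p21 <- add_pt(a[2L], b[1L])
      tri <- rbind(tri, c(p11, p12, p22), c(p11, p22, p21))
      tet_of <- c(tet_of, e, e)
    }
  }
  pts <- nodes[ip1, , drop = FALSE] * (1 - ww) + nodes[ip2, , drop = FALSE] * ww
  e1 <- pts[tri[, 2L], , drop = FALSE] - pts[tri[, 1L], , drop = FALSE]
  e2 <- pts[tri[, 3L], , drop = FALSE] - pts[tri[, 1L], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sqrt(rowSums(cr^2)) / 2
  list(points = pts, i1 = ip1, i2 = ip2, w = ww, tri = tri,
       tri_area = area, tet_of = tet_of, area = sum(area))
}

## Interpolate nodal values (vector or N x k matrix) at the cut points.
slice_values <- function(cut, nodal) {
  if (is.null(dim(nodal))) nodal <- matrix(nodal, ncol = 1L)
  nodal[cut$i1, , drop = FALSE] * (1 - cut$w) + nodal[cut$i2, , drop = FALSE] * cut$w
}

## integral of a nodal field over the cut (per column).
slice_integral <- function(cut, nodal) {
  v <- slice_values(cut, nodal)
  vt <- (v[cut$tri[, 1L], , drop = FALSE] + v[cut$tri[, 2L], , drop = FALSE] +
         v[cut$tri[, 3L], , drop = FALSE]) / 3
  colSums(vt * cut$tri_area)
}

slice_flux <- function(nodes, tets, u, slice, region_tags = NULL) {
  cut <- slice_cut(nodes, tets, slice, region_tags)
  sum(slice_integral(cut, u) * slice$normal)
}

slice_average_pressure <- function(nodes, tets, p, slice, region_tags = NULL) {
  cut <- slice_cut(nodes, tets, slice, region_tags)
  slice_integral(cut, p) / cut$area
}

#' Flow rate through a slice over a simulation
#'
#' `Q(t) = integral of u . n` over the in-plane cross-section of the moved
#' mesh at each stored step; the sign convention follows the slice normal
#' (aortic slice: outflow positive; mitral slice oriented toward the atrium:
#' regurgitant flow positive).
#'
#' @param history a `flow_history` from [solve_flow()].
#' @param slice a [plane_slice()] (meters).
#' @return data.frame with `t` (s) and `q_ml_s` (mL/s).
#' @export
slice_flow_rate <- function(history, slice) {
  dom <- history$domain
  q <- vapply(seq_along(history$times), function(s) {
    nodes <- dom$nodes0 + history$d[s, , ]
    slice_flux(nodes, dom$tets, history$u[s, , ], slice, dom$region)
  }, numeric(1))
  data.frame(t = history$times, q_ml_s = q * 1e6)
}

#' Slice-averaged pressures over a simulation
#' @param history a `flow_history`.
#' @param slice a [plane_slice()].
#' @return data.frame with `t` and `p_mmhg`.
#' @export
slice_pressure_series <- function(history, slice) {
  dom <- history$domain
  p <- vapply(seq_along(history$times), function(s) {
    nodes <- dom$nodes0 + history$d[s, , ]
    slice_average_pressure(nodes, dom$tets, history$p[s, ], slice, dom$region)
  }, numeric(1))
  data.frame(t = history$times, p_mmhg = p / MMHG_TO_PA)
}

## trapezoid integral
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Ejection timing features from the LVOT flow-rate curve
#'
#' `t_v1` and `t_v2` are the two most prominent local maxima (ascending in
#' time, prominence-based with a minimum separation of `0.05 T_S`, earlier
#' peak wins ties), and `t_dec = (t_v2 + t_c)/2` is the instant of middle
#' deceleration.
#'
#' @param times,q flow-rate series.
#' @param t_c aortic valve closure time (s).
#' @param t_s systole duration (for the separation rule; defaults to the
#'   record length).
#' @return list `t_v1`, `t_v2`, `t_dec`, `single_peak`.
#' @export
timing_features <- function(times, q, t_c, t_s = max(times)) {
  n <- length(q)
  cand <- which(diff(sign(diff(q))) < 0) + 1L
  if (q[1L] > q[2L]) cand <- c(1L, cand)
  if (q[n] > q[n - 1L]) cand <- c(cand, n)
  prominence <- vapply(cand, function(i) {
    left <- if (any(q[seq_len(i)] > q[i])) {
      j <- max(which(q[seq_len(i)] > q[i]))
      min(q[j:i])
    } else min(q[seq_len(i)])
    right <- if (any(q[i:n] > q[i])) {
      j <- i - 1L + min(which(q[i:n] > q[i]))
      min(q[i:j])
    } else min(q[i:n])
    q[i] - max(left, right)
  }, numeric(1))
  ord <- cand[order(-prominence, times[cand])]
  sel <- integer(0)
  for (i in ord) {
    if (all(abs(times[i] - times[sel]) >= 0.05 * t_s)) sel <- c(sel, i)
    if (length(sel) == 2L) break
  }
  if (length(sel) < 2L) {
    pk <- times[sel[1L]]
    return(list(t_v1 = pk, t_v2 = pk, t_dec = (pk + t_c) / 2, single_peak = TRUE))
  }
  pk <- sort(times[sel])
  list(t_v1 = pk[1L], t_v2 = pk[2L], t_dec = (pk[2L] + t_c) / 2,
       single_peak = FALSE)
}

#' Clinical volume indices
#'
#' Stroke volume as the time integral of the LVOT flow rate; regurgitant
#' volume as the time integral of the atrium-directed (positive) mitral
#' flow; cardiac output `CO = SV x HR / 1000`; regurgitant fraction
#' `RF = 100 RV / (SV + RV)`.  An RV below the RIIS leakage threshold
#' (default 3% of total ejected volume) is clinically indistinguishable from
#' numerical valve leakage, so RF is reported as 0 in that case.
#'
#' @param times time grid (s).
#' @param q_lvot,q_mv flow-rate series (mL/s; mitral positive = regurgitant).
#' @param hr_bpm heart rate (1/min).
#' @param leak_frac leakage threshold as a fraction of `SV + RV`.
#' @return list `sv_ml`, `rv_ml`, `co_l_min`, `rf_pct`.
#' @export
compute_indices <- function(times, q_lvot, q_mv, hr_bpm, leak_frac = 0.03) {
  sv <- trapz(times, q_lvot)
  if (sv < 0) stop("negative stroke volume: check the slice sign convention")
  rv <- trapz(times, pmax(q_mv, 0))
  co <- sv * hr_bpm / 1000
  rf <- if (rv < leak_frac * (sv + rv)) 0 else 100 * rv / (sv + rv)
  list(sv_ml = sv, rv_ml = rv, co_l_min = co, rf_pct = rf)
}

#' Mean systolic ventriculo-aortic pressure drop
#'
#' Time average over the ejection window `[t_o, t_c]` of the difference of
#' the slice-averaged ventricular and aortic pressures.
#'
#' @param times time grid (s).
#' @param p_vent,p_aorta slice-averaged pressures (mmHg).
#' @param t_o,t_c opening and closure instants (s), `t_c > t_o`.
#' @return list `dp` (series over the window) and `dp_mean` (mmHg).
#' @export
pressure_metrics <- function(times, p_vent, p_aorta, t_o, t_c) {
  if (t_c <= t_o) stop("t_c must exceed t_o")
  dp <- p_vent - p_aorta
  tt <- sort(unique(c(t_o, times[times > t_o & times < t_c], t_c)))
  dpw <- approx(times, dp, xout = tt, rule = 2)$y
  list(dp = data.frame(t = times, dp_mmhg = dp),
       dp_mean = trapz(tt, dpw) / (t_c - t_o))
}

#' Maximum velocity magnitude at a slice over a run
#' @param history a `flow_history`.
#' @param slice a [plane_slice()].
#' @param stride evaluate every `stride`-th stored step.
#' @return maximum over time and slice points of |u| (m/s).
#' @export
velocity_maxima <- function(history, slice, stride = 1L) {
  dom <- history$domain
  max(vapply(seq(1L, length(history$times), by = stride), function(s) {
    nodes <- dom$nodes0 + history$d[s, , ]
    cut <- slice_cut(nodes, dom$tets, slice, dom$region)
    max(sqrt(rowSums(slice_values(cut, history$u[s, , ])^2)))
  }, numeric(1)))
}

#' Atrial turbulence ratio
#'
#' Volume-weighted spatial mean over a cell mask (the atrium) of
#' `mu_sgs / mu` per step, and its time average `R_bar`.
#'
#' The atrium region is the atrial side above the mitral annulus plane (the
#' part of the atrial chamber downstream of the closed valve).
#'
#' @param history a `flow_history`.
#' @param mask logical or index vector over cells; by default, atrial-region
#'   cells whose centroid lies above the mitral annulus plane.
#' @param mu physical viscosity (Pa s); defaults to the run's.
#' @return list `r` (data.frame `t`, `ratio`) and `r_bar`.
#' @export
turbulence_ratio <- function(history, mask = NULL, mu = NULL) {
  dom <- history$domain
  if (is.null(mask)) mask <- atrium_mask(history)
  if (is.logical(mask)) mask <- which(mask)
  if (!length(mask)) stop("empty atrium mask")
  if (is.null(mu)) mu <- history$props$mu
  r <- vapply(seq_along(history$times), function(s) {
    nodes <- dom$nodes0 + history$d[s, , ]
    v <- tet_volumes(nodes, dom$tets)[mask]
    sum(history$musgs[s, mask] * v) / sum(v) / mu
  }, numeric(1))
  list(r = data.frame(t = history$times, ratio = r),
       r_bar = trapz(history$times, r) / diff(range(history$times)))
}

#' Wall shear stress on a tagged wall or an immersed valve surface
#'
#' The WSS vector is the tangential part of the viscous traction
#' `(I - n n^T) (2 mu_eff D(u) n)` with `mu_eff = mu + mu_sgs`, evaluated
#' from the cell velocity gradient owning each wall face (or containing each
#' valve-surface sample point).  Returns the magnitude field, its spatial
#' mean, and a histogram over configurable bins.
#'
#' @param nodes,tets current mesh (m).
#' @param u nodal velocity (m/s).
#' @param musgs_cell per-cell subgrid viscosity (Pa s).
#' @param mu physical viscosity (Pa s).
#' @param surface either `list(type = "wall", faces =, owner =)` (faces with
#'   owning cells, outward normals) or `list(type = "immersed", verts =,
#'   tris =)` for a valve surface sampled at triangle centroids.
#' @param breaks inner histogram break points (Pa); bins are
#'   `[0, b1), [b1, b2), ..., [bk, Inf)`.
#' @return list `wss` (per sample), `mean`, `hist` (counts), `breaks`.
#' @export
wall_shear_stress <- function(nodes, tets, u, musgs_cell, mu, surface,
                              breaks = c(2, 4, 6)) {
  cg <- cpp_cell_gradients(nodes, tets, u)
  if (surface$type == "wall") {
    fa <- face_normals_areas(nodes, surface$faces)
    own <- surface$owner
    nrm <- fa$normal
    G <- cg$grad[own, , drop = FALSE]
    mu_eff <- mu + musgs_cell[own]
  } else {
    cent <- (surface$verts[surface$tris[, 1L], , drop = FALSE] +
             surface$verts[surface$tris[, 2L], , drop = FALSE] +
             surface$verts[surface$tris[, 3L], , drop = FALSE]) / 3
    fa <- face_normals_areas(surface$verts, surface$tris)
    nrm <- fa$normal
    loc <- cpp_locate_points(nodes, tets, cent, 1e-6)
    ok <- loc$elem > 0L
    if (!any(ok)) stop("immersed surface lies outside the mesh")
    nrm <- nrm[ok, , drop = FALSE]
    G <- cg$grad[loc$elem[ok], , drop = FALSE]
    mu_eff <- mu + musgs_cell[loc$elem[ok]]
  }
  if (any(!is.finite(nrm))) stop("degenerate surface normals")
  ## traction t = 2 mu_eff D n ; D = (G + G^T)/2, G row-major
  tx <- mu_eff * ((2 * G[, 1L]) * nrm[, 1L] + (G[, 2L] + G[, 4L]) * nrm[, 2L] + (G[, 3L] + G[, 7L]) * nrm[, 3L])
  ty <- mu_eff * ((G[, 4L] + G[, 2L]) * nrm[, 1L] + (2 * G[, 5L]) * nrm[, 2L] + (G[, 6L] + G[, 8L]) * nrm[, 3L])
  tz <- mu_eff * ((G[, 7L] + G[, 3L]) * nrm[, 1L] + (G[, 8L] + G[, 6L]) * nrm[, 2L] + (2 * G[, 9L]) * nrm[, 3L])
  tn <- tx * nrm[, 1L] + ty * nrm[, 2L] + tz * nrm[, 3L]
  wx <- tx - tn * nrm[, 1L]; wy <- ty - tn * nrm[, 2L]; wz <- tz - tn * nrm[, 3L]
  wss <- sqrt(wx^2 + wy^2 + wz^2)
  br <- c(0, breaks, Inf)
  h <- table(cut(wss, br, right = FALSE))
  list(wss = wss, mean = mean(wss), hist = as.integer(h), breaks = br)
}

## cells of the anatomical atrium: atrial region above the annulus plane
atrium_mask <- function(history) {
  dom <- history$domain
  z_ann <- annulus_plane_z(history)
  cent_z <- (dom$nodes0[dom$tets[, 1L], 3L] + dom$nodes0[dom$tets[, 2L], 3L] +
             dom$nodes0[dom$tets[, 3L], 3L] + dom$nodes0[dom$tets[, 4L], 3L]) / 4
  dom$region == 2L & cent_z > z_ann
}

annulus_plane_z <- function(history) {
  v <- history$valves
  if (is.null(v)) return(-Inf)
  ann <- v$surface$annulus_idx
  mean(v$surface$nodes[ann, 3L]) * 1e-3
}

#' Time-averaged WSS summaries over a run
#'
#' @param history a `flow_history`.
#' @param what `"wall"` (atrial wall above the annulus plane) or `"mitral"`
#'   (the immersed mitral valve at its advected position).
#' @param breaks histogram inner breaks (Pa).
#' @param stride evaluate every `stride`-th stored step (the spatial WSS
#'   extraction is the most expensive postprocessing step).
#' @return list `mean_t` (series), `wss_bar` (time average of the spatial
#'   mean), `hist` at the step of peak mean.
#' @export
wss_summary <- function(history, what = c("wall", "mitral"),
                        breaks = if (match.arg(what) == "mitral") c(2, 4, 6) else c(3, 6, 9, 12),
                        stride = 1L) {
  what <- match.arg(what)
  dom <- history$domain
  if (what == "wall") {
    sel <- dom$face_tag == 1L
    ## atrial wall above the annulus plane
    sel <- sel & dom$region[history$domain$geom$face_owner] == 2L
    z_ann <- annulus_plane_z(history)
    fcent <- (dom$nodes0[dom$faces[, 1L], 3L] + dom$nodes0[dom$faces[, 2L], 3L] +
              dom$nodes0[dom$faces[, 3L], 3L]) / 3
    sel <- sel & fcent > z_ann
    faces <- dom$faces[sel, , drop = FALSE]
    owner <- history$domain$geom$face_owner[sel]
  }
  steps <- seq(1L, length(history$times), by = stride)
  means <- numeric(length(steps))
  hist_best <- NULL; best <- -Inf
  for (k in seq_along(steps)) {
    s <- steps[k]
    nodes <- dom$nodes0 + history$d[s, , ]
    surf <- if (what == "wall")
      list(type = "wall", faces = faces, owner = owner)
    else
      list(type = "immersed", verts = history$mitral_pos[[s]],
           tris = history$valves$mitral$tris)
    w <- wall_shear_stress(nodes, dom$tets, history$u[s, , ],
                           history$musgs[s, ], history$props$mu, surf,
                           breaks = breaks)
    means[k] <- w$mean
    if (w$mean > best) { best <- w$mean; hist_best <- w }
  }
  tt <- history$times[steps]
  list(mean_t = data.frame(t = tt, wss_pa = means),
       wss_bar = trapz(tt, means) / diff(range(tt)),
       hist = hist_best$hist, breaks = hist_best$breaks)
}
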