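## ---------------------------------------------------------------------------
## Mitral valve reconstruction: radial-plane leaflet traces -> ordered point
## cloud -> ring-wise periodic B-spline fitting -> leaflet surface mesh ->
## wall attachment -> distance field and smoothed-delta layer for the
## resistive immersed surface (RIIS) penalty.
## ---------------------------------------------------------------------------

#' Assemble the ordered valve point cloud from radial-plane traces
#'
#' Stacks the 18 x 2 leaflet profiles (32 samples each) into the canonical
#' 1152 x 3 matrix: profiles sorted by the azimuth of their annulus point
#' about the annulus axis, sample-major within each profile (row
#' `(p-1)*32 + j` is sample `j` of profile `p`).  Ring `j` of the cloud is
#' the set of the 36 profiles' `j`-th points; ring 1 is the annulus and ring
#' 32 the free margin.
#'
#' @param traces a `valve_traces` object (see [generate_valve_traces()] /
#'   [read_traces_csv()]).
#' @return object of class `valve_point_cloud` with `raw` (1152 x 3),
#'   `n_samples`, `n_profiles`, `azimuth`, `center`, `axis`.
#' @export
assemble_point_cloud <- function(traces) {
  planes <- traces$planes
  if (length(planes) != 18L)
    stop("expected 18 radial planes, got ", length(planes))
  profs <- list()
  leaflet <- character(0)
  for (pl in planes) {
    if (!all(dim(pl$anterior) == c(32L, 3L)) || !all(dim(pl$posterior) == c(32L, 3L)))
      stop("each leaflet profile must have 32 points")
    profs[[length(profs) + 1L]] <- pl$anterior
    profs[[length(profs) + 1L]] <- pl$posterior
    leaflet <- c(leaflet, "anterior", "posterior")
  }
  ctr <- traces$center
  az <- vapply(profs, function(m) {
    d <- m[1L, ] - ctr
    (atan2(d[2L], d[1L]) + 2 * pi) %% (2 * pi)
  }, numeric(1))
  ord <- order(az)
  raw <- do.call(rbind, profs[ord])
  structure(list(raw = raw, n_samples = 32L, n_profiles = 36L,
                 azimuth = az[ord], leaflet = leaflet[ord], center = ctr,
                 axis = if (is.null(traces$axis)) c(0, 0, 1) else traces$axis,
                 resampled = NULL, n_ring_pts = NULL),
            class = "valve_point_cloud")
}

#' Ring-blocked view of a valve point cloud
#' @param cloud a `valve_point_cloud`.
#' @param ring ring index (1 = annulus ... 32 = free margin).
#' @return 36 x 3 matrix of the ring's points in profile order.
#' @export
ring_view <- function(cloud, ring) {
  stopifnot(ring >= 1L, ring <= cloud$n_samples)
  cloud$raw[ring + cloud$n_samples * (seq_len(cloud$n_profiles) - 1L), , drop = FALSE]
}

## Periodic cubic B-spline design matrix with K uniformly spaced basis
## functions on [0, 1).
periodic_bspline_basis <- function(u, K) {
  knots <- seq(-3, K + 3) / K
  B <- splines::splineDesign(knots, x = u %% 1, ord = 4L, outer.ok = TRUE)
  for (j in 1:3) B[, j] <- B[, j] + B[, j + K]
  B[, seq_len(K), drop = FALSE]
}

## Cyclic second-difference penalty.
cyclic_penalty <- function(K) {
  D <- matrix(0, K, K)
  for (j in seq_len(K)) {
    D[j, j] <- -2
    D[j, (j %% K) + 1L] <- 1
    D[j, ((j - 2L) %% K) + 1L] <- 1
  }
  crossprod(D)
}

## Fit one closed ring: periodic cubic smoothing spline per coordinate over
## a uniform parameter (one knot interval per input point, which keeps the
## collocation well conditioned for arbitrarily clustered points); resample
## at n_out uniform parameter values.
fit_one_ring <- function(pts, n_out = 1000L, lambda = 0) {
  n <- nrow(pts)
  seg <- sqrt(rowSums((pts[c(2:n, 1L), ] - pts)^2))
  L <- sum(seg)
  if (L < 1e-9 || qr(scale(pts, scale = FALSE))$rank < 2L)
    stop("degenerate ring: collinear or duplicated points")
  u <- (seq_len(n) - 1L) / n
  K <- n
  B <- periodic_bspline_basis(u, K)
  A <- crossprod(B)
  ## a tiny curvature-penalty floor keeps the system nonsingular when points
  ## coincide (duplicated coaptation rows); it perturbs distinct-point
  ## interpolation far below trace precision
  A <- A + max(lambda, 1e-8) * cyclic_penalty(K)
  cf <- solve(A, crossprod(B, pts))
  uu <- (seq_len(n_out) - 1L) / n_out
  periodic_bspline_basis(uu, K) %*% cf
}

#' Fit and resample the valve rings
#'
#' Fits each of the 32 rings with a closed periodic cubic smoothing spline
#' (penalized B-spline with a cyclic second-difference penalty) over a
#' uniform parameter, and resamples it at 1000 uniformly spaced
#' parameter values, giving the canonical 32,000 x 3 cloud.
#'
#' The smoothing weight follows a fixed rule scaled to the trace noise
#' variance: `lambda = n_points * noise_sd^2 / mean_chord^2`, so noiseless
#' input (`noise_sd = 0`) is interpolated exactly.
#'
#' Near the annulus a ring is traversed in azimuthal order; near the free
#' margin of a coapting valve the ring degenerates to the coaptation arc
#' traversed once per leaflet, which requires reversing the anterior block.
#' How the two leaflets' profiles interleave into a ring traversal is not
#' dictated by the tracing protocol, so each ring picks, between the two
#' canonical family orderings (anterior block forward or reversed), the one
#' with the shorter closed polygon; both extremes are handled exactly and
#' the bridging chords lie on the leaflet surface (the commissure diameter
#' belongs to the anterior leaflet).
#'
#' @param cloud a `valve_point_cloud`.
#' @param noise_sd expected isotropic noise of the trace points (mm).
#' @param n_ring_pts resampled points per ring.
#' @return the cloud with `$resampled` (32,000 x 3) and `$n_ring_pts` set.
#' @export
fit_rings <- function(cloud, noise_sd = 0, n_ring_pts = 1000L) {
  n <- cloud$n_samples
  ## the anterior profiles form one cyclically contiguous block in azimuth
  ## order; build the alternative traversal with that block reversed
  ord1 <- seq_len(cloud$n_profiles)
  ord2 <- ord1
  if (!is.null(cloud$leaflet)) {
    ant <- which(cloud$leaflet == "anterior")
    ## rotate so the anterior block is contiguous (not wrapping)
    if (length(ant) > 0L && length(ant) < cloud$n_profiles) {
      isant <- cloud$leaflet == "anterior"
      np <- cloud$n_profiles
      ## find a rotation where all anterior indices are consecutive
      for (r in 0:(np - 1L)) {
        rot <- ((seq_len(np) - 1L + r) %% np) + 1L
        w <- which(isant[rot])
        if (all(diff(w) == 1L)) { ord1 <- rot; break }
      }
      ord2 <- ord1
      w <- which(isant[ord1])
      ord2[w] <- rev(ord1[w])
    }
  }
  closed_len <- function(p) {
    m <- nrow(p)
    sum(sqrt(rowSums((p[c(2:m, 1L), ] - p)^2)))
  }
  res <- vector("list", n)
  prev <- NULL
  for (j in seq_len(n)) {
    pts <- ring_view(cloud, j)
    p1 <- pts[ord1, , drop = FALSE]
    p2 <- pts[ord2, , drop = FALSE]
    pts <- if (closed_len(p2) < closed_len(p1)) p2 else p1
    seg <- sqrt(rowSums((pts[c(2:nrow(pts), 1L), ] - pts)^2))
    mean_chord <- mean(seg[seg > 0])
    lambda <- if (noise_sd > 0) nrow(pts) * noise_sd^2 / mean_chord^2 else 0
    cur <- fit_one_ring(pts, n_out = n_ring_pts, lambda = lambda)
    if (!is.null(prev)) cur <- align_ring(cur, prev)
    res[[j]] <- cur
    prev <- cur
  }
  cloud$resampled <- do.call(rbind, res)   # ring-major: 1000 rows per ring
  cloud$n_ring_pts <- as.integer(n_ring_pts)
  cloud
}

## Cyclically shift (and possibly reverse) a resampled ring to best match the
## previous ring point-by-point, so the structured surface grid does not
## twist between rings.
align_ring <- function(cur, prev) {
  n <- nrow(cur)
  step <- max(1L, n %/% 100L)
  sub <- seq(1L, n, by = step)
  score <- function(r) sum(rowSums((r[sub, , drop = FALSE] - prev[sub, , drop = FALSE])^2))
  best <- NULL; bestsc <- Inf
  for (dir in c(1L, -1L)) {
    r0 <- if (dir == 1L) cur else cur[c(1L, n:2L), , drop = FALSE]
    ## coarse shift search then fine
    coarse <- seq(0L, n - 1L, by = step)
    sc <- vapply(coarse, function(s) score(r0[((seq_len(n) - 1L + s) %% n) + 1L, , drop = FALSE]), numeric(1))
    s0 <- coarse[which.min(sc)]
    fine <- (s0 - step):(s0 + step)
    for (s in fine) {
      r <- r0[((seq_len(n) - 1L + s) %% n) + 1L, , drop = FALSE]
      v <- score(r)
      if (v < bestsc) { bestsc <- v; best <- r }
    }
  }
  best
}

resampled_ring <- function(cloud, ring) {
  stopifnot(!is.null(cloud$resampled))
  cloud$resampled[(ring - 1L) * cloud$n_ring_pts + seq_len(cloud$n_ring_pts), , drop = FALSE]
}

## Leaflet-sheet surface construction.  The closed mitral membrane is a
## star-shaped "dome" over the annulus: radial sections at anterior azimuths
## run from the annulus to the coaptation crease on the opposite side;
## sections at posterior azimuths consist of the anterior leaflet from the
## center out to the crease plus the posterior leaflet from the crease to
## the posterior annulus.  The surface is built as an inner fan (center ->
## annulus or crease) welded along the crease to a posterior sector sheet,
## which is watertight for a coapting valve and opens a genuine orifice
## window where a prolapsed posterior segment leaves the crease.
build_surface_leaflets <- function(cloud, weld_tol = 1.5, noise_sd = 0,
                                   n_rad = 14L, n_out = 8L) {
  stopifnot(!is.null(cloud$leaflet))
  np <- cloud$n_profiles; ns <- cloud$n_samples
  ctr <- cloud$center
  prof <- lapply(seq_len(np), function(p)
    cloud$raw[(p - 1L) * ns + seq_len(ns), , drop = FALSE])
  if (noise_sd > 0) {
    prof <- lapply(prof, function(m) {
      for (k in 1:3) {
        fit <- stats::smooth.spline(seq_len(ns), m[, k], df = 10)
        sm <- stats::predict(fit, seq_len(ns))$y
        sm[1L] <- m[1L, k]; sm[ns] <- m[ns, k]
        m[, k] <- sm
      }
      m
    })
  }
  isant <- cloud$leaflet == "anterior"
  az <- cloud$azimuth
  ## signed radius of each profile point along its plane direction
  tsign <- lapply(seq_len(np), function(p) {
    u <- c(cos(az[p]), sin(az[p]), 0)
    as.numeric(sweep(prof[[p]], 2L, ctr, "-") %*% u)
  })
  ## pair each posterior profile with the anterior one of the same plane
  ant_ids <- which(isant); post_ids <- which(!isant)
  pair_of_post <- vapply(post_ids, function(pp) {
    target <- (az[pp] + pi) %% (2 * pi)
    d <- abs((az[ant_ids] - target + pi) %% (2 * pi) - pi)
    ant_ids[which.min(d)]
  }, integer(1))

  interp_profile <- function(p, tq) {
    tv <- tsign[[p]]
    ord <- order(tv)
    sapply(1:3, function(k) approx(tv[ord], prof[[p]][ord, k], xout = tq,
                                   rule = 2, ties = list("ordered", mean))$y)
  }
  ## inner column per azimuth: outer radius and the sampler
  R_inner <- numeric(np); sampler <- vector("list", np)
  for (p in seq_len(np)) {
    if (isant[p]) {
      R_inner[p] <- max(tsign[[p]])
      local_p <- p
      sampler[[p]] <- local({pp <- local_p; function(rq) interp_profile(pp, rq)})
    } else {
      pa <- pair_of_post[match(p, post_ids)]
      R_inner[p] <- -min(tsign[[pa]])   # crease radius from the anterior data
      local_pa <- pa
      sampler[[p]] <- local({pp <- local_pa; function(rq) interp_profile(pp, -rq)})
    }
  }
  ## center node: mean of the anterior sections at t = 0
  center <- colMeans(do.call(rbind, lapply(ant_ids, function(p)
    interp_profile(p, 0))))

  nodes <- matrix(center, 1L, 3L)
  idx_in <- matrix(0L, n_rad, np)   # ring j (1..n_rad), azimuth column p
  for (p in seq_len(np)) {
    rq <- (seq_len(n_rad)) / n_rad * R_inner[p]
    pts <- sampler[[p]](rq)
    idx_in[, p] <- nrow(nodes) + seq_len(n_rad)
    nodes <- rbind(nodes, pts)
  }
  tris <- list()
  nxt <- c(2:np, 1L)
  tris[[1L]] <- cbind(1L, idx_in[1L, ], idx_in[1L, nxt])
  for (j in seq_len(n_rad - 1L))
    tris[[j + 1L]] <- rbind(cbind(idx_in[j, ], idx_in[j, nxt], idx_in[j + 1L, nxt]),
                            cbind(idx_in[j, ], idx_in[j + 1L, nxt], idx_in[j + 1L, ]))
  annulus <- idx_in[n_rad, isant]

  ## posterior sector sheet: columns from crease (row 0) to annulus
  ## (row n_out).  Columns are built for all azimuths cyclically; anterior
  ## azimuths collapse to their annulus node, which closes the commissure
  ## wedges with triangle fans automatically.
  idx_out <- matrix(0L, n_out + 1L, np)
  for (p in seq_len(np)) {
    if (isant[p]) {
      idx_out[, p] <- idx_in[n_rad, p]
      next
    }
    m <- prof[[p]][ns:1, , drop = FALSE]   # crease first
    seg <- sqrt(rowSums((m[-1L, , drop = FALSE] - m[-ns, , drop = FALSE])^2))
    sarc <- c(0, cumsum(seg))
    if (sarc[ns] < 1e-9) {               # degenerate commissural column
      idx_out[, p] <- idx_in[n_rad, p]
      next
    }
    stgt <- (0:n_out) / n_out * sarc[ns]
    pts <- sapply(1:3, function(c2) approx(sarc, m[, c2], xout = stgt, rule = 2,
                                           ties = list("ordered", mean))$y)
    ## weld the crease end onto the inner boundary node of the same azimuth
    inner_node <- idx_in[n_rad, p]
    gap <- sqrt(sum((pts[1L, ] - nodes[inner_node, ])^2))
    if (gap <= weld_tol) {
      idx_out[1L, p] <- inner_node
      first <- 2L
    } else first <- 1L
    ids <- nrow(nodes) + seq_len(n_out + 2L - first)
    nodes <- rbind(nodes, pts[first:(n_out + 1L), , drop = FALSE])
    if (first == 2L) idx_out[2:(n_out + 1L), p] <- ids
    else idx_out[, p] <- ids
  }
  for (k in seq_len(np)) {
    k2 <- if (k == np) 1L else k + 1L
    tris[[length(tris) + 1L]] <-
      rbind(cbind(idx_out[-(n_out + 1L), k], idx_out[-1L, k], idx_out[-1L, k2]),
            cbind(idx_out[-(n_out + 1L), k], idx_out[-1L, k2], idx_out[-(n_out + 1L), k2]))
  }
  annulus <- c(annulus, idx_out[n_out + 1L, ])
  tris <- do.call(rbind, tris)
  fa <- face_normals_areas(nodes, tris)
  keep <- fa$area > 1e-9 * max(fa$area)
  tris <- tris[keep, , drop = FALSE]
  el <- rbind(nodes[tris[, 1L], ] - nodes[tris[, 2L], ],
              nodes[tris[, 2L], ] - nodes[tris[, 3L], ],
              nodes[tris[, 3L], ] - nodes[tris[, 1L], ])
  elen <- sqrt(rowSums(el^2))
  structure(list(nodes = nodes, tris = tris,
                 annulus_idx = unique(annulus), n_az = np, n_rings = n_rad,
                 edge_cv = stats::sd(elen) / mean(elen)),
            class = "valve_surface")
}

#' Build the leaflet surface mesh from the resampled cloud
#'
#' Connects the 32 resampled rings with a structured quad grid at a uniform
#' target edge length (the azimuthal sample count is chosen from the mean
#' ring circumference), triangulated along minimum-index diagonals.  Rings
#' are resampled at equal arc length to even out edge sizes.
#'
#' @param cloud a fitted `valve_point_cloud`.
#' @param target_edge_mm target edge length (mm).
#' @param n_az optional explicit azimuthal sample count (overrides
#'   `target_edge_mm`).
#' @param relax_iters iterations of tangential Laplacian relaxation
#'   (projected back onto the surface); keep 0 for coapting valves.
#' @return object of class `valve_surface`: `nodes` (mm), `tris`,
#'   `annulus_idx` (node indices of ring 1), `edge_cv`.
#' @export
build_surface <- function(cloud, target_edge_mm = 2.5, n_az = NULL,
                          relax_iters = 0L) {
  stopifnot(!is.null(cloud$resampled))
  nr_all <- cloud$n_samples
  circum <- vapply(seq_len(nr_all), function(j) {
    r <- resampled_ring(cloud, j)
    sum(sqrt(rowSums((r[c(2:nrow(r), 1L), ] - r)^2)))
  }, numeric(1))
  if (is.null(n_az)) n_az <- max(12L, round(mean(circum) / target_edge_mm))
  ## equal-arclength azimuthal resample of every ring at n_az points
  ring_nodes <- lapply(seq_len(nr_all), function(j) {
    r <- resampled_ring(cloud, j)
    n <- nrow(r)
    seg <- sqrt(rowSums((r[c(2:n, 1L), ] - r)^2))
    s <- c(0, cumsum(seg))
    stgt <- (seq_len(n_az) - 1L) / n_az * s[n + 1L]
    idx <- findInterval(stgt, s, rightmost.closed = TRUE)
    idx[idx > n] <- n
    w <- (stgt - s[idx]) / pmax(seg[idx], 1e-30)
    r[idx, , drop = FALSE] * (1 - w) + r[c(2:n, 1L), , drop = FALSE][idx, , drop = FALSE] * w
  })
  ## radial resample along each azimuth column at equal arc length, so edge
  ## sizes stay near the target even though profile lengths vary around the
  ## valve ("remesh with a uniform edge length")
  col_len <- vapply(seq_len(n_az), function(k) {
    p <- t(vapply(ring_nodes, function(rn) rn[k, ], numeric(3)))
    sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nr_all, , drop = FALSE])^2)))
  }, numeric(1))
  ## near-equilateral strips: radial spacing = sqrt(3)/2 of the azimuthal
  ## step, odd rows staggered by half a step
  n_rad <- max(3L, round(mean(col_len) / (0.866 * target_edge_mm)))
  new_rows <- lapply(0:n_rad, function(i) matrix(0, n_az, 3L))
  for (k in seq_len(n_az)) {
    p <- t(vapply(ring_nodes, function(rn) rn[k, ], numeric(3)))
    seg <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nr_all, , drop = FALSE])^2))
    s <- c(0, cumsum(seg))
    stgt <- (0:n_rad) / n_rad * s[nr_all]
    idx <- pmin(findInterval(stgt, s, rightmost.closed = TRUE), nr_all - 1L)
    w <- (stgt - s[idx]) / pmax(seg[idx], 1e-30)
    pt <- p[idx, , drop = FALSE] * (1 - w) + p[idx + 1L, , drop = FALSE] * w
    for (i in 0:n_rad) new_rows[[i + 1L]][k, ] <- pt[i + 1L, ]
  }
  shift_half <- function(row) {
    m <- nrow(row)
    seg <- sqrt(rowSums((row[c(2:m, 1L), ] - row)^2))
    s <- c(0, cumsum(seg))
    stgt <- (s[-(m + 1L)] + s[-1L]) / 2
    idx <- pmin(findInterval(stgt, s, rightmost.closed = TRUE), m)
    w <- (stgt - s[idx]) / pmax(seg[idx], 1e-30)
    nxt <- c(2:m, 1L)
    row[idx, , drop = FALSE] * (1 - w) + row[nxt, , drop = FALSE][idx, , drop = FALSE] * w
  }
  for (i in seq(2L, n_rad + 1L, by = 2L)) new_rows[[i]] <- shift_half(new_rows[[i]])
  nr <- n_rad + 1L
  nodes <- do.call(rbind, new_rows)
  tris <- list()
  nxt <- c(2:n_az, 1L)
  idr <- function(j) (j - 1L) * n_az   # row offset, j = 1..nr
  for (j in seq_len(nr - 1L)) {
    lower_shifted <- (j %% 2L == 0L)   # rows 2,4,... are staggered
    if (!lower_shifted) {
      ## row j at integer steps, row j+1 at half steps
      tris[[length(tris) + 1L]] <- rbind(
        cbind(idr(j) + seq_len(n_az), idr(j) + nxt, idr(j + 1L) + seq_len(n_az)),
        cbind(idr(j) + nxt, idr(j + 1L) + nxt, idr(j + 1L) + seq_len(n_az)))
    } else {
      tris[[length(tris) + 1L]] <- rbind(
        cbind(idr(j) + seq_len(n_az), idr(j + 1L) + nxt, idr(j + 1L) + seq_len(n_az)),
        cbind(idr(j) + seq_len(n_az), idr(j) + nxt, idr(j + 1L) + nxt))
    }
  }
  tris <- do.call(rbind, tris)
  ## optional isotropic relaxation: Laplacian smoothing of interior nodes
  ## projected back onto the reference surface.  Off by default: on a fully
  ## coapting (doubled-sheet) valve the closest-point projection can hop to
  ## the opposing leaflet and flatten the bag.
  if (relax_iters > 0L) {
    fixed <- c(seq_len(n_az), (nr - 1L) * n_az + seq_len(n_az))
    ref_nodes <- nodes; ref_tris <- tris
    ed <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3L, 1L)])
    ed <- unique(rbind(ed, ed[, 2:1]))
    adj <- split(ed[, 2L], ed[, 1L])
    interior <- setdiff(seq_len(nrow(nodes)), fixed)
    for (it in seq_len(relax_iters)) {
      targ <- t(vapply(interior, function(i) colMeans(nodes[adj[[as.character(i)]], , drop = FALSE]), numeric(3)))
      proj <- cpp_closest_on_surface(targ, ref_nodes, ref_tris)
      nodes[interior, ] <- proj$point
    }
  }
  ## drop degenerate (zero-area) triangles from coincident coaptation points
  fa <- face_normals_areas(nodes, tris)
  keep <- fa$area > 1e-10 * max(fa$area)
  tris <- tris[keep, , drop = FALSE]
  el <- rbind(nodes[tris[, 1L], ] - nodes[tris[, 2L], ],
              nodes[tris[, 2L], ] - nodes[tris[, 3L], ],
              nodes[tris[, 3L], ] - nodes[tris[, 1L], ])
  elen <- sqrt(rowSums(el^2))
  structure(list(nodes = nodes, tris = tris,
                 annulus_idx = seq_len(n_az), n_az = as.integer(n_az),
                 n_rings = nr,
                 edge_cv = stats::sd(elen) / mean(elen)),
            class = "valve_surface")
}

## Extend the valve surface radially past its annulus ring ("skirt"), so the
## immersed membrane overlaps the wall and the rim cannot leak between the
## polyline annulus and the faceted wall.  Skirt nodes typically lie outside
## the fluid domain; their quadrature samples are simply dropped there.
add_annulus_skirt <- function(valve, width = 2.5) {
  ann <- valve$annulus_idx
  ctr <- colMeans(valve$nodes[ann, , drop = FALSE])
  d <- sweep(valve$nodes[ann, 1:2, drop = FALSE], 2L, ctr[1:2], "-")
  rr <- sqrt(rowSums(d^2))
  dir <- cbind(d / rr, 0)
  skirt <- valve$nodes[ann, , drop = FALSE] + width * dir
  az <- atan2(d[, 2L], d[, 1L])
  ord <- order(az)
  n0 <- nrow(valve$nodes)
  valve$nodes <- rbind(valve$nodes, skirt[ord, , drop = FALSE])
  a <- ann[ord]; b <- n0 + seq_along(ann)
  nxt <- c(2:length(a), 1L)
  valve$tris <- rbind(valve$tris,
                      cbind(a, a[nxt], b[nxt]),
                      cbind(a, b[nxt], b))
  valve$skirt_idx <- b
  valve
}

#' Warp a valve surface onto the wall (harmonic gap extension)
#'
#' Computes, for each annulus node, the vector to its closest point on the
#' wall surface, extends this boundary field harmonically over the valve
#' surface (combinatorial graph Laplacian, which satisfies a discrete
#' maximum principle), and warps the valve accordingly.
#'
#' @param valve a `valve_surface`.
#' @param wall_nodes,wall_tris wall surface mesh (mm).
#' @param max_gap_mm hard failure threshold for the annulus-wall distance.
#' @return the warped `valve_surface` (with `$warp` attached).
#' @export
attach_to_wall <- function(valve, wall_nodes, wall_tris, max_gap_mm = 10) {
  ann <- valve$annulus_idx
  cp <- cpp_closest_on_surface(valve$nodes[ann, , drop = FALSE],
                               wall_nodes, wall_tris)
  if (max(cp$dist) > max_gap_mm)
    stop(sprintf("annulus lies %.2f mm from the wall (threshold %.1f mm)",
                 max(cp$dist), max_gap_mm))
  gap <- cp$point - valve$nodes[ann, , drop = FALSE]
  n <- nrow(valve$nodes)
  ## surface edge graph
  ed <- rbind(valve$tris[, 1:2], valve$tris[, 2:3], valve$tris[, c(3L, 1L)])
  ed <- unique(rbind(ed, ed[, 2:1]))
  ii <- ed[, 1L]; jj <- ed[, 2L]
  L <- sparseMatrix(i = ii, j = jj, x = rep(-1, length(ii)), dims = c(n, n))
  deg <- -Matrix::rowSums(L)
  L <- L + Diagonal(n, deg)
  free <- setdiff(seq_len(n), ann)
  warp <- matrix(0, n, 3L)
  warp[ann, ] <- gap
  if (length(free)) {
    Lff <- L[free, free, drop = FALSE]
    rhs <- -L[free, ann, drop = FALSE] %*% gap
    warp[free, ] <- as.matrix(Matrix::solve(Lff, rhs))
  }
  valve$nodes <- valve$nodes + warp
  valve$warp <- warp
  valve
}

#' Smoothed Dirac delta layer of an immersed surface
#'
#' Unsigned Euclidean distance `phi` from each query point to the surface
#' (exact nearest-triangle distance) and the cosine-smoothed delta
#' `delta = (1 + cos(pi phi / eps)) / (2 eps)` for `|phi| <= eps`, zero
#' outside; its 1-D integral across the layer is 1 and its peak is `1/eps`.
#'
#' @param verts,tris immersed surface mesh.
#' @param points query points (solver nodes), same units as `verts`.
#' @param eps layer half-thickness (same units).
#' @param cap optional distance beyond which exact distances are not needed
#'   (pruning accelerator); values above `cap` may be reported as `cap`.
#'   Must exceed `eps`.
#' @return list with `phi` and `delta`.
#' @export
distance_and_delta <- function(verts, tris, points, eps, cap = 4 * eps) {
  if (!is.null(cap) && cap <= eps) stop("cap must exceed eps")
  phi <- cpp_dist_to_surface(points, verts, tris, if (is.null(cap)) -1 else cap)
  delta <- ifelse(phi <= eps, (1 + cos(pi * phi / eps)) / (2 * eps), 0)
  list(phi = phi, delta = delta)
}

#' Immersed valve description for the flow solver
#'
#' @param nodes_mm,tris surface mesh in mm (converted to meters internally).
#' @param eps_m layer half-thickness in meters (default 0.75 mm).
#' @param R resistance (kg/(m s), default 1e4).
#' @param state `"closed"` or `"open"`.
#' @param name label.
#' @return object of class `immersed_valve` (nodes stored in meters).
#' @export
immersed_valve <- function(nodes_mm, tris, eps_m = 7.5e-4, R = 1e4,
                           state = c("closed", "open"), name = "valve") {
  state <- match.arg(state)
  stopifnot(eps_m > 0, R > 0)
  structure(list(nodes = nodes_mm * 1e-3, tris = tris, eps = eps_m, R = R,
                 state = state, name = name, u_gamma = 0),
            class = "immersed_valve")
}

## Aortic valve template surfaces, built analytically inside the aortic tube.
## closed: a gently domed membrane spanning the duct; open: a thin sleeve
## hugging the wall (the three open leaflets folded back), which leaves the
## lumen unobstructed.
aortic_templates <- function(geom, s_av = 0.35, n_ring = 6L, n_az = 24L) {
  spec <- geom$spec; mod <- geom$model
  z_av <- s_av * spec$ao_h
  r_duct <- mod$r_ao(s_av)
  ctr_ref <- c(mod$cx_ao(s_av), 0, z_av)
  th <- (seq_len(n_az) - 1L) / n_az * 2 * pi
  ## closed: polar cap, extended 12% past the duct wall so the rim seals
  rs <- seq_len(n_ring) / n_ring * 1.12 * r_duct
  dome <- function(r) 0.2 * r_duct * (1 - (r / (1.12 * r_duct))^2)
  nodes <- rbind(c(0, 0, dome(0)),
                 do.call(rbind, lapply(rs, function(r)
                   cbind(r * cos(th), r * sin(th), dome(r)))))
  tris <- list()
  tris[[1L]] <- cbind(1L, 1L + seq_len(n_az), 1L + c(2:n_az, 1L))
  for (j in seq_len(n_ring - 1L)) {
    i0 <- 1L + (j - 1L) * n_az; i1 <- 1L + j * n_az
    nxt <- c(2:n_az, 1L)
    q <- cbind(i0 + seq_len(n_az), i0 + nxt, i1 + nxt, i1 + seq_len(n_az))
    tris[[j + 1L]] <- rbind(q[, c(1L, 2L, 3L)], q[, c(1L, 3L, 4L)])
  }
  closed_nodes <- sweep(nodes, 2L, ctr_ref, "+")
  closed <- list(nodes = from_reference(geom, closed_nodes), tris = do.call(rbind, tris))
  ## open: wall-hugging sleeve
  zs <- seq(z_av - 0.5 * r_duct, z_av + 0.5 * r_duct, length.out = 5L)
  sl_nodes <- do.call(rbind, lapply(zs, function(z) {
    s <- z / spec$ao_h
    r <- 0.97 * mod$r_ao(s)
    cbind(mod$cx_ao(s) + r * cos(th), r * sin(th), z)
  }))
  sl_tris <- list()
  for (j in seq_len(length(zs) - 1L)) {
    i0 <- (j - 1L) * n_az; i1 <- j * n_az
    nxt <- c(2:n_az, 1L)
    q <- cbind(i0 + seq_len(n_az), i0 + nxt, i1 + nxt, i1 + seq_len(n_az))
    sl_tris[[j]] <- rbind(q[, c(1L, 2L, 3L)], q[, c(1L, 3L, 4L)])
  }
  open <- list(nodes = from_reference(geom, sl_nodes), tris = do.call(rbind, sl_tris))
  list(closed = closed, open = open, center = from_reference(geom, matrix(ctr_ref, 1L))[1L, ],
       r_duct = r_duct * spec$dilation, z_av = z_av)
}

#' Build the immersed valves of a scenario
#'
#' Scenario H uses the healthy (coapting) mitral valve and starts with the
#' aortic valve open; R1 uses the P2-prolapse mitral valve; R2 is the R1
#' valve dilated by 1.25 together with the geometry.  The mitral valve is
#' always closed; the aortic valve carries both an open and a closed
#' template for the on/off switching.
#'
#' @param scenario `"H"`, `"R1"` or `"R2"`.
#' @param geom phantom geometry built with the scenario's dilation and valve
#'   kind (see [scenario_config()]).
#' @param traces optional precomputed `valve_traces`.
#' @param noise_sd trace noise used for ring smoothing (mm).
#' @param eps_m,R RIIS layer half-thickness (m) and resistance (kg/(m s)).
#' @param target_edge_mm mitral surface mesh resolution.
#' @return list with `mitral` (`immersed_valve`, closed), `aortic_open`,
#'   `aortic_closed` (`immersed_valve`s), `cloud`, `surface`, `templates`.
#' @export
make_scenario_valves <- function(scenario = c("H", "R1", "R2"), geom,
                                 traces = NULL, noise_sd = NULL,
                                 eps_m = 7.5e-4, R = 1e4,
                                 target_edge_mm = 2.5) {
  scenario <- match.arg(scenario)
  spec <- geom$spec
  expected_valve <- if (scenario == "H") "healthy" else "prolapse"
  if (spec$valve != expected_valve)
    stop(sprintf("scenario %s needs a %s valve in the phantom spec", scenario, expected_valve))
  if (scenario == "R2" && spec$dilation != 1.25)
    stop("scenario R2 requires dilation 1.25")
  if (is.null(traces)) traces <- generate_valve_traces(spec, geom)
  if (is.null(noise_sd)) noise_sd <- spec$trace_noise_mm
  cloud <- assemble_point_cloud(traces)
  cloud <- fit_rings(cloud, noise_sd = noise_sd)
  ## the immersed membrane uses the leaflet-sheet construction, which keeps
  ## the coaptation seam and any regurgitant window topologically exact; the
  ## ring-grid surface remains available for generic (single-sheet) clouds
  surf <- build_surface_leaflets(cloud, noise_sd = noise_sd)
  wall_faces <- geom$faces[geom$face_tag == 1L, , drop = FALSE]
  surf <- attach_to_wall(surf, geom$nodes, wall_faces)
  skirted <- add_annulus_skirt(surf)
  mitral <- immersed_valve(skirted$nodes, skirted$tris, eps_m = eps_m, R = R,
                           state = "closed", name = "mitral")
  tpl <- aortic_templates(geom)
  ao_open <- immersed_valve(tpl$open$nodes, tpl$open$tris, eps_m = eps_m, R = R,
                            state = "open", name = "aortic")
  ao_closed <- immersed_valve(tpl$closed$nodes, tpl$closed$tris, eps_m = eps_m, R = R,
                              state = "closed", name = "aortic")
  ## regurgitant orifice region (meters): centroid and radius of the margin
  ## gap, used by the solver to keep the channel free of extra stabilization
  orifice_center <- NULL; orifice_radius <- NULL; orifice_anchor <- NULL
  gaps <- lapply(traces$planes, function(p)
    list(g = sqrt(sum((p$anterior[32L, ] - p$posterior[32L, ])^2)),
         mid = (p$anterior[32L, ] + p$posterior[32L, ]) / 2))
  gv <- vapply(gaps, function(x) x$g, numeric(1))
  if (any(gv > 1)) {
    pts <- do.call(rbind, lapply(gaps[gv > 1], function(x) x$mid))
    orifice_center <- colMeans(pts) * 1e-3
    orifice_radius <- (max(sqrt(rowSums(sweep(pts, 2L, colMeans(pts))^2))) +
                       0.25 * max(gv)) * 1e-3
    orifice_anchor <- which.min(rowSums(sweep(skirted$nodes * 1e-3, 2L,
                                              orifice_center)^2))
  }
  list(mitral = mitral, aortic_open = ao_open, aortic_closed = ao_closed,
       cloud = cloud, surface = surf, templates = tpl,
       orifice_center = orifice_center, orifice_radius = orifice_radius,
       orifice_anchor = orifice_anchor,
       scenario = scenario)
}
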