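#' @useDynLib cardioriis, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom Matrix sparseMatrix Cholesky solve t Diagonal
#' @importFrom stats splinefun uniroot rnorm integrate approx
#' @importFrom utils read.csv write.csv head tail
NULL

## ---------------------------------------------------------------------------
## Structured mesh primitives.  All tet meshes are stored as
## list(nodes = N x 3, tets = M x 4 (1-based), ...) with positively oriented
## tets.  Units are whatever the caller uses (geometry code works in mm).
## ---------------------------------------------------------------------------

## Butterfly ("O-grid") triangulation of the unit disc.
## ns: cells per half-side of the core square (core has 2*ns cells per side),
## nr: radial cell layers between square and circle.
## Boundary has 8*ns nodes; mesh is symmetric about x = 0 and y = 0 and no
## triangle crosses the line x = 0.
disc_butterfly <- function(ns = 3L, nr = 2L, square = 0.5) {
  s <- square
  n2 <- 2L * ns
  ## core square grid
  g <- seq(-s, s, length.out = n2 + 1L)
  core <- as.matrix(expand.grid(x = g, y = g))
  pts <- list(core)
  quads <- list()
  id <- function(i, j) (j - 1L) * (n2 + 1L) + i  # core indexing
  q <- matrix(0L, n2 * n2, 4L)
  k <- 1L
  for (j in seq_len(n2)) for (i in seq_len(n2)) {
    q[k, ] <- c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L), id(i, j + 1L))
    k <- k + 1L
  }
  quads[[1L]] <- q
  off <- nrow(core)
  ## four side blocks: edge param t in [0,1] along square edge (2*ns cells),
  ## radial param r in (0,1] (nr cells, layer r=0 is the square edge itself,
  ## already in `core`).
  blocks <- list(
    list(edge = function(t) cbind(s, -s + 2 * s * t),  ang = function(t) (-45 + 90 * t) * pi / 180),
    list(edge = function(t) cbind(s - 2 * s * t, s),   ang = function(t) (45 + 90 * t) * pi / 180),
    list(edge = function(t) cbind(-s, s - 2 * s * t),  ang = function(t) (135 + 90 * t) * pi / 180),
    list(edge = function(t) cbind(-s + 2 * s * t, -s), ang = function(t) (225 + 90 * t) * pi / 180)
  )
  allpts <- core
  for (b in blocks) {
    t <- seq(0, 1, length.out = n2 + 1L)
    for (ir in seq_len(nr)) {
      r <- ir / nr
      arc <- cbind(cos(b$ang(t)), sin(b$ang(t)))
      lay <- (1 - r) * b$edge(t) + r * arc
      allpts <- rbind(allpts, lay)
    }
  }
  ## weld duplicates (block corners are generated bit-identically twice)
  key <- paste(sprintf("%.10f", allpts[, 1]), sprintf("%.10f", allpts[, 2]))
  first <- !duplicated(key)
  map <- match(key, key[first])
  nodes <- allpts[first, , drop = FALSE]
  ## block quads
  bq <- list(q)
  base <- nrow(core)
  for (ib in seq_along(blocks)) {
    b <- blocks[[ib]]
    t <- seq(0, 1, length.out = n2 + 1L)
    ## row index helper: radial layer 0 = square edge points (in core),
    ## layers 1..nr are appended sequentially.
    lay_id <- function(ir, it) {
      if (ir == 0L) {
        e <- b$edge(t[it])
        ## exact grid point of core
        i <- round((e[1] + s) / (2 * s) * n2) + 1L
        j <- round((e[2] + s) / (2 * s) * n2) + 1L
        id(i, j)
      } else {
        base + ((ib - 1L) * nr + (ir - 1L)) * (n2 + 1L) + it
      }
    }
    qb <- matrix(0L, n2 * nr, 4L)
    k <- 1L
    for (ir in seq_len(nr)) for (it in seq_len(n2)) {
      qb[k, ] <- c(lay_id(ir - 1L, it), lay_id(ir - 1L, it + 1L),
                   lay_id(ir, it + 1L), lay_id(ir, it))
      k <- k + 1L
    }
    bq[[ib + 1L]] <- qb
  }
  quads <- do.call(rbind, bq)
  quads[] <- map[quads]
  ## triangulate each quad along its min-index diagonal (deterministic)
  t1 <- quads[, c(1L, 2L, 3L)]
  t2 <- quads[, c(1L, 3L, 4L)]
  alt <- pmin(quads[, 2L], quads[, 4L]) < pmin(quads[, 1L], quads[, 3L])
  t1[alt, ] <- quads[alt, c(1L, 2L, 4L)]
  t2[alt, ] <- quads[alt, c(2L, 3L, 4L)]
  tris <- rbind(t1, t2)
  ## fix 2-D orientation (CCW)
  a <- nodes[tris[, 1L], ]; b2 <- nodes[tris[, 2L], ]; c2 <- nodes[tris[, 3L], ]
  ar <- (b2[, 1] - a[, 1]) * (c2[, 2] - a[, 2]) - (b2[, 2] - a[, 2]) * (c2[, 1] - a[, 1])
  flip <- ar < 0
  tris[flip, c(2L, 3L)] <- tris[flip, c(3L, 2L)]
  list(xy = nodes, tris = tris)
}

## Split a stack of triangle layers (prisms) into tets with globally
## consistent diagonals (minimum-global-index rule).
## layer_nodes: list of K coordinate matrices (same row count n, matching
## rows across layers).  tri: the layer triangulation (rows into 1..n).
## Returns nodes ((K*n) x 3) and tets.
extrude_tri_stack <- function(layer_nodes, tri) {
  K <- length(layer_nodes)
  n <- nrow(layer_nodes[[1L]])
  nodes <- do.call(rbind, layer_nodes)
  tets <- vector("list", K - 1L)
  for (k in seq_len(K - 1L)) {
    off0 <- (k - 1L) * n
    off1 <- k * n
    b <- tri + off0   # bottom triangle vertices
    t <- tri + off1   # top
    tets[[k]] <- split_prisms(b, t)
  }
  tets <- do.call(rbind, tets)
  tets <- orient_tets(nodes, tets)
  list(nodes = nodes, tets = tets)
}

## Split prisms (bottom rows b, top rows t, t[i] above b[i]) into 3 tets each
## using the min-vertex diagonal rule, which is conforming across prisms.
split_prisms <- function(b, t) {
  m <- nrow(b)
  out <- matrix(0L, 3L * m, 4L)
  for (e in seq_len(m)) {
    v <- c(b[e, ], t[e, ])  # v[1:3] bottom, v[4:6] top
    ## rotate/flip so the smallest global index sits at position 1 (bottom)
    imin <- which.min(v)
    if (imin > 3L) { v <- v[c(4L, 6L, 5L, 1L, 3L, 2L)]; imin <- which.min(v) }
    rot <- switch(imin, c(1L, 2L, 3L, 4L, 5L, 6L),
                        c(2L, 3L, 1L, 5L, 6L, 4L),
                        c(3L, 1L, 2L, 6L, 4L, 5L))
    v <- v[rot]
    ## faces adjacent to v1 get diagonals v1-v5 and v1-v6; the third quad
    ## face (v2 v3 v6 v5) gets the diagonal through its smallest vertex.
    if (min(v[2L], v[6L]) < min(v[3L], v[5L])) {
      tts <- rbind(c(v[1L], v[2L], v[3L], v[6L]),
                   c(v[1L], v[2L], v[6L], v[5L]),
                   c(v[1L], v[5L], v[6L], v[4L]))
    } else {
      tts <- rbind(c(v[1L], v[2L], v[3L], v[5L]),
                   c(v[1L], v[5L], v[3L], v[6L]),
                   c(v[1L], v[5L], v[6L], v[4L]))
    }
    out[(3L * e - 2L):(3L * e), ] <- tts
  }
  out
}

#' Signed tetrahedron volumes
#' @param nodes,tets tet mesh.
#' @return vector of volumes (positive for well-oriented cells).
#' @export
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1L], , drop = FALSE]
  b <- nodes[tets[, 2L], , drop = FALSE] - a
  c2 <- nodes[tets[, 3L], , drop = FALSE] - a
  d <- nodes[tets[, 4L], , drop = FALSE] - a
  (b[, 1] * (c2[, 2] * d[, 3] - c2[, 3] * d[, 2]) -
   b[, 2] * (c2[, 1] * d[, 3] - c2[, 3] * d[, 1]) +
   b[, 3] * (c2[, 1] * d[, 2] - c2[, 2] * d[, 1])) / 6
}

orient_tets <- function(nodes, tets) {
  v <- tet_volumes(nodes, tets)
  flip <- v < 0
  tets[flip, c(3L, 4L)] <- tets[flip, c(4L, 3L)]
  tets
}

#' Boundary faces of a tet mesh, oriented outward
#'
#' Errors if the mesh is not watertight (a face shared by more than two
#' cells).
#' @param nodes,tets tet mesh.
#' @return list `faces` (outward-oriented boundary triangles) and `owner`.
#' @export
mesh_boundary <- function(nodes, tets) {
  fidx <- rbind(tets[, c(1L, 3L, 2L)], tets[, c(1L, 2L, 4L)],
                tets[, c(2L, 3L, 4L)], tets[, c(1L, 4L, 3L)])
  owner <- rep(seq_len(nrow(tets)), 4L)
  key <- apply(fidx, 1L, function(r) paste(sort(r), collapse = "_"))
  cnt <- table(key)
  if (any(cnt > 2L))
    stop("non-watertight tet mesh: a face is shared by more than two cells")
  bnd <- key %in% names(cnt)[cnt == 1L]
  list(faces = fidx[bnd, , drop = FALSE], owner = owner[bnd])
}

#' Unit normals, areas and centroids of surface triangles
#' @param nodes,faces triangle surface.
#' @export
face_normals_areas <- function(nodes, faces) {
  a <- nodes[faces[, 1L], , drop = FALSE]
  b <- nodes[faces[, 2L], , drop = FALSE]
  c2 <- nodes[faces[, 3L], , drop = FALSE]
  e1 <- b - a; e2 <- c2 - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- sqrt(rowSums(n^2))
  list(normal = n / area2, area = area2 / 2,
       centroid = (a + b + c2) / 3)
}

#' Volume enclosed by a closed triangle surface (divergence theorem)
#' @param nodes,faces outward-oriented closed triangle surface.
#' @return enclosed volume.
#' @export
surface_enclosed_volume <- function(nodes, faces) {
  a <- nodes[faces[, 1L], , drop = FALSE]
  b <- nodes[faces[, 2L], , drop = FALSE]
  c2 <- nodes[faces[, 3L], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c2[, 3] - b[, 3] * c2[, 2]) -
      a[, 2] * (b[, 1] * c2[, 3] - b[, 3] * c2[, 1]) +
      a[, 3] * (b[, 1] * c2[, 2] - b[, 2] * c2[, 1])) / 6
}

#' Total area of a triangle surface
#' @param nodes,faces triangle surface.
#' @export
surface_total_area <- function(nodes, faces) {
  sum(face_normals_areas(nodes, faces)$area)
}

## Nodal volumes (lumped mass): each tet contributes V/4 to its vertices.
nodal_volumes <- function(nodes, tets, vol = NULL) {
  if (is.null(vol)) vol <- tet_volumes(nodes, tets)
  nv <- numeric(nrow(nodes))
  for (k in 1:4) {
    agg <- rowsum(vol / 4, tets[, k])
    ids <- as.integer(rownames(agg))
    nv[ids] <- nv[ids] + agg[, 1L]
  }
  nv
}

## ---------------------------------------------------------------------------
## Simple structured meshes used by solver verification problems.
## ---------------------------------------------------------------------------

#' Structured tetrahedral box mesh
#'
#' Kuhn split (6 tets per cube, conforming) of an axis-aligned box defined by
#' grid coordinate vectors, which may be non-uniform to grade resolution.
#'
#' @param x,y,z strictly increasing grid coordinate vectors.
#' @return A tet mesh: `list(nodes, tets)`.
#' @export
box_mesh <- function(x, y, z) {
  nx <- length(x); ny <- length(y); nz <- length(z)
  nodes <- as.matrix(expand.grid(x = x, y = y, z = z))
  id <- function(i, j, k) (k - 1L) * nx * ny + (j - 1L) * nx + i
  perms <- rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                 c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  tets <- vector("list", 6L)
  grid3 <- expand.grid(i = seq_len(nx - 1L), j = seq_len(ny - 1L), k = seq_len(nz - 1L))
  for (p in seq_len(6L)) {
    pr <- perms[p, ]
    ## Kuhn path 0 -> e_{pr1} -> e_{pr1}+e_{pr2} -> (1,1,1)
    off <- matrix(0L, 4L, 3L)
    off[2L, pr[1L]] <- 1L
    off[3L, pr[1L]] <- 1L; off[3L, pr[2L]] <- 1L
    off[4L, ] <- 1L
    tets[[p]] <- cbind(id(grid3$i + off[1L, 1L], grid3$j + off[1L, 2L], grid3$k + off[1L, 3L]),
                       id(grid3$i + off[2L, 1L], grid3$j + off[2L, 2L], grid3$k + off[2L, 3L]),
                       id(grid3$i + off[3L, 1L], grid3$j + off[3L, 2L], grid3$k + off[3L, 3L]),
                       id(grid3$i + off[4L, 1L], grid3$j + off[4L, 2L], grid3$k + off[4L, 3L]))
  }
  tets <- orient_tets(nodes, do.call(rbind, tets))
  list(nodes = nodes, tets = tets)
}

#' Structured tetrahedral cylinder mesh
#'
#' Butterfly-disc cross-section extruded along z, suitable for channel-flow
#' verification problems.
#'
#' @param radius cylinder radius.
#' @param z vector of layer z-coordinates (may be graded).
#' @param ns,nr butterfly-disc resolution parameters.
#' @return tet mesh with `$disc` (the 2-D section) attached.
#' @export
cylinder_mesh <- function(radius, z, ns = 3L, nr = 2L) {
  d <- disc_butterfly(ns, nr)
  layers <- lapply(z, function(zz) cbind(d$xy * radius, zz))
  m <- extrude_tri_stack(layers, d$tris)
  m$disc <- d
  m
}

## ---------------------------------------------------------------------------
## Plain-text mesh / field writers (ASCII STL, legacy VTK).
## ---------------------------------------------------------------------------

#' Write a triangulated surface as ASCII STL
#' @param nodes vertex coordinates (n x 3).
#' @param tris triangle index matrix (m x 3, 1-based).
#' @param path output file.
#' @export
write_stl <- function(nodes, tris, path) {
  fn <- face_normals_areas(nodes, tris)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid surface", con)
  for (i in seq_len(nrow(tris))) {
    writeLines(sprintf("facet normal %g %g %g", fn$normal[i, 1], fn$normal[i, 2], fn$normal[i, 3]), con)
    writeLines(" outer loop", con)
    for (v in tris[i, ])
      writeLines(sprintf("  vertex %g %g %g", nodes[v, 1], nodes[v, 2], nodes[v, 3]), con)
    writeLines(" endloop", con)
    writeLines("endfacet", con)
  }
  writeLines("endsolid surface", con)
  invisible(path)
}

#' Write a mesh with optional point data as legacy ASCII VTK
#'
#' Accepts a tet mesh (cells with 4 indices) or a triangle surface (3).
#'
#' @param nodes vertex coordinates.
#' @param cells index matrix (m x 3 or m x 4, 1-based).
#' @param path output file.
#' @param point_data named list of numeric vectors (scalars) or 3-column
#'   matrices (vectors) defined on nodes.
#' @export
write_vtk <- function(nodes, cells, path, point_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- ncol(cells)
  ctype <- if (nv == 4L) 10L else 5L
  writeLines(c("# vtk DataFile Version 3.0", "cardioriis mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", nrow(nodes)), con)
  writeLines(apply(nodes, 1L, function(r) paste(format(r, digits = 10), collapse = " ")), con)
  writeLines(sprintf("CELLS %d %d", nrow(cells), nrow(cells) * (nv + 1L)), con)
  writeLines(apply(cells, 1L, function(r) paste(c(nv, r - 1L), collapse = " ")), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(cells)), con)
  writeLines(as.character(rep(ctype, nrow(cells))), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(nodes)), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v) && ncol(v) == 3L) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(apply(v, 1L, function(r) paste(format(r, digits = 8), collapse = " ")), con)
      } else {
        writeLines(sprintf("SCALARS %s double 1", nm), con)
        writeLines("LOOKUP_TABLE default", con)
        writeLines(format(as.numeric(v), digits = 8), con)
      }
    }
  }
  invisible(path)
}
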