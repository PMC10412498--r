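test_that("the assembled cloud has the canonical 1152 rows and azimuth order", {
  cl <- assemble_point_cloud(fix_traces())
  expect_equal(dim(cl$raw), c(1152L, 3L))
  expect_equal(cl$n_samples * cl$n_profiles, 1152L)
  expect_true(all(diff(cl$azimuth) > 0))
  ## ring view: ring 1 is the annulus at constant height
  ann <- ring_view(cl, 1L)
  expect_equal(dim(ann), c(36L, 3L))
  expect_lt(diff(range(ann[, 3L])), 1e-9)
})

test_that("permuted plane input yields the identical cloud after azimuth sorting", {
  tr <- fix_traces()
  tr2 <- tr
  tr2$planes <- tr$planes[sample(18L)]
  expect_identical(assemble_point_cloud(tr)$raw, assemble_point_cloud(tr2)$raw)
})

test_that("ring fitting recovers a circle and interpolates noiseless points", {
  th <- (0:35) / 36 * 2 * pi
  r0 <- 5
  circ <- cbind(r0 * cos(th), r0 * sin(th), 0)
  fit <- cardioriis:::fit_one_ring(circ, n_out = 1000L, lambda = 0)
  expect_lt(max(abs(sqrt(rowSums(fit[, 1:2]^2)) - r0)) / r0, 1e-3)
  ## interpolation limit: evaluate back at the sample parameters
  B <- cardioriis:::periodic_bspline_basis((0:35) / 36, 36L)
  A <- crossprod(B) + 1e-8 * cardioriis:::cyclic_penalty(36L)
  cf <- solve(A, crossprod(B, circ))
  expect_lt(max(abs(B %*% cf - circ)), 1e-6)
})

test_that("the resampled cloud has 32,000 rows and deviates from truth within the noise", {
  cl <- fix_cloud()
  expect_equal(dim(cl$resampled), c(32000L, 3L))
  expect_equal(cl$n_ring_pts, 1000L)
  ## smoothing scaled to the noise keeps the fitted curve within the trace
  ## noise of the true ring: noisy out-of-plane circles across several seeds
  sigma <- 0.3
  r0 <- 15
  th <- (0:35) / 36 * 2 * pi
  ring <- cbind(r0 * cos(th), r0 * sin(th), 2 * sin(2 * th))
  thf <- seq(0, 2 * pi, length.out = 4000L)
  truth <- cbind(r0 * cos(thf), r0 * sin(thf), 2 * sin(2 * thf))
  lam <- 36 * sigma^2 / ((2 * pi * r0 / 36)^2)   # the fixed smoothing rule
  for (s in 1:4) {
    set.seed(s)
    noisy <- ring + matrix(rnorm(36 * 3, 0, sigma), 36L, 3L)
    fit <- cardioriis:::fit_one_ring(noisy, 1000L, lam)
    dev <- mean(vapply(seq(1L, 1000L, by = 10L), function(i)
      sqrt(min(rowSums(sweep(truth, 2L, fit[i, ])^2))), numeric(1)))
    expect_lt(dev, sigma)
  }
})

test_that("ring fitting is equivariant under rotation and translation", {
  cl <- fix_cloud()
  th <- 0.7
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3L, 3L,
               byrow = TRUE)
  shift <- c(3, -2, 5)
  tr <- fix_traces()
  tr2 <- tr
  tr2$planes <- lapply(tr$planes, function(p) {
    p$anterior <- sweep(p$anterior %*% t(Rz), 2L, shift, "+")
    p$posterior <- sweep(p$posterior %*% t(Rz), 2L, shift, "+")
    p
  })
  tr2$center <- as.numeric(Rz %*% tr$center + shift)
  cl2 <- fit_rings(assemble_point_cloud(tr2))
  expect_equal(cl2$resampled,
               sweep(cl$resampled %*% t(Rz), 2L, shift, "+"),
               tolerance = 1e-9)
})

test_that("degenerate rings are rejected", {
  pts <- matrix(rep(c(1, 2, 3), each = 36), 36L, 3L)
  expect_error(cardioriis:::fit_one_ring(pts), "degenerate")
})

test_that("the ring-grid surface recovers a spherical zone area and converges", {
  r0 <- 10
  rings <- lapply(seq(0, 0.98 * pi / 2, length.out = 32L), function(ph) {
    th <- (0:35) / 36 * 2 * pi
    cbind(r0 * cos(ph) * cos(th), r0 * cos(ph) * sin(th), r0 * sin(ph))
  })
  raw <- matrix(0, 1152L, 3L)
  for (j in 1:32) for (p in 1:36) raw[(p - 1L) * 32L + j, ] <- rings[[j]][p, ]
  cl <- structure(list(raw = raw, n_samples = 32L, n_profiles = 36L,
                       leaflet = NULL, center = c(0, 0, 0), axis = c(0, 0, 1)),
                  class = "valve_point_cloud")
  cl <- fit_rings(cl)
  exact <- 2 * pi * r0^2 * sin(0.98 * pi / 2)
  s1 <- build_surface(cl, target_edge_mm = 1)
  expect_lt(abs(surface_total_area(s1$nodes, s1$tris) - exact) / exact, 0.02)
  expect_lt(s1$edge_cv, 0.3)
  s2 <- build_surface(cl, target_edge_mm = 0.5)
  a1 <- surface_total_area(s1$nodes, s1$tris)
  a2 <- surface_total_area(s2$nodes, s2$tris)
  expect_lt(abs(a2 - a1) / a1, 0.005)
})

test_that("wall attachment closes the annulus gap and obeys the maximum principle", {
  g <- fix_geom()
  cl <- fix_cloud()
  surf <- cardioriis:::build_surface_leaflets(cl)
  wall <- g$faces[g$face_tag == 1L, , drop = FALSE]
  pre_gap <- cardioriis:::cpp_closest_on_surface(
    surf$nodes[surf$annulus_idx, , drop = FALSE], g$nodes, wall)$dist
  expect_gt(max(pre_gap), 0.1)
  warped <- attach_to_wall(surf, g$nodes, wall)
  post_gap <- cardioriis:::cpp_closest_on_surface(
    warped$nodes[warped$annulus_idx, , drop = FALSE], g$nodes, wall)$dist
  expect_lt(max(post_gap), 0.1)
  ## interior warp bounded by the boundary extremes (discrete max principle)
  wmag <- sqrt(rowSums(warped$warp^2))
  expect_lte(max(wmag), max(wmag[warped$annulus_idx]) + 1e-9)
})

test_that("a uniform gap warps the valve by a uniform translation", {
  ## plane wall 1 mm above a flat square valve
  gx <- seq(0, 10, by = 1)
  grid <- as.matrix(expand.grid(x = gx, y = gx))
  n <- nrow(grid)
  nodesv <- cbind(grid, 0)
  id <- function(i, j) (j - 1L) * length(gx) + i
  quads <- do.call(rbind, lapply(seq_len(length(gx) - 1L), function(j)
    t(vapply(seq_len(length(gx) - 1L), function(i)
      c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L), id(i, j + 1L)), integer(4)))))
  tris <- rbind(quads[, c(1, 2, 3)], quads[, c(1, 3, 4)])
  valve <- structure(list(nodes = nodesv, tris = tris,
                          annulus_idx = which(grid[, 1] %in% range(gx) |
                                              grid[, 2] %in% range(gx))),
                     class = "valve_surface")
  ## a fine wall plane at z = 1
  wx <- seq(-2, 12, by = 0.5)
  wgrid <- as.matrix(expand.grid(x = wx, y = wx))
  wn <- cbind(wgrid, 1)
  wid <- function(i, j) (j - 1L) * length(wx) + i
  wq <- do.call(rbind, lapply(seq_len(length(wx) - 1L), function(j)
    t(vapply(seq_len(length(wx) - 1L), function(i)
      c(wid(i, j), wid(i + 1L, j), wid(i + 1L, j + 1L), wid(i, j + 1L)), integer(4)))))
  wt <- rbind(wq[, c(1, 2, 3)], wq[, c(1, 3, 4)])
  warped <- attach_to_wall(valve, wn, wt)
  expect_equal(warped$warp, matrix(rep(c(0, 0, 1), each = n), n, 3L),
               tolerance = 1e-9)
  ## zero gap: identity warp
  valve0 <- valve; valve0$nodes[, 3] <- 1
  warped0 <- attach_to_wall(valve0, wn, wt)
  expect_lt(max(abs(warped0$warp)), 1e-9)
})

test_that("the smoothed delta layer has the exact peak, support and unit integral", {
  ## a single flat triangle as the surface
  verts <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  tris <- matrix(c(1L, 2L, 3L), 1L)
  eps <- 2
  z <- seq(-4, 4, by = 0.01)
  pts <- cbind(2, 2, z)
  dd <- distance_and_delta(verts, tris, pts, eps, cap = NULL)
  expect_equal(dd$phi, abs(z), tolerance = 1e-12)
  expect_equal(max(dd$delta), 1 / eps)              # phi = 0 -> 1/eps
  expect_true(all(dd$delta[abs(z) > eps] == 0))     # compact support
  expect_true(all(dd$delta >= 0))
  ## unit integral across the layer by quadrature
  i1 <- sum(dd$delta) * 0.01
  expect_lt(abs(i1 - 1), 1e-4)
})

test_that("delta-layer volume approximates the leaflet area at solver resolution", {
  g <- fix_geom()
  v <- make_scenario_valves("H", g)
  nodes_m <- g$nodes * 1e-3
  eps <- 2.5e-3
  dd <- distance_and_delta(v$surface$nodes * 1e-3, v$surface$tris, nodes_m, eps)
  nv <- cardioriis:::nodal_volumes(nodes_m, g$tets)
  layer_vol <- sum(dd$delta * nv)
  area <- surface_total_area(v$surface$nodes * 1e-3, v$surface$tris)
  expect_lt(abs(layer_vol - area) / area, 0.25)
})

test_that("scenario valves encode the H/R1/R2 construction", {
  g <- fix_geom()
  vH <- make_scenario_valves("H", g)
  expect_s3_class(vH$mitral, "immersed_valve")
  expect_equal(vH$mitral$state, "closed")
  expect_equal(vH$mitral$eps, 7.5e-4)
  expect_equal(vH$mitral$R, 1e4)
  expect_error(make_scenario_valves("R1", g), "needs")
  sp1 <- phantom_spec(valve = "prolapse", trace_noise_mm = 0, mesh = coarse_mesh_cfg())
  g1 <- generate_geometry(sp1)
  t1 <- generate_valve_traces(sp1, g1)
  sp2 <- phantom_spec(valve = "prolapse", dilation = 1.25, trace_noise_mm = 0,
                      mesh = coarse_mesh_cfg())
  g2 <- generate_geometry(sp2)
  t2 <- generate_valve_traces(sp2, g2)
  ## R2 orifice area = R1 orifice area x 1.25^2
  expect_equal(t2$orifice_area_mm2 / t1$orifice_area_mm2, 1.25^2)
  v2 <- make_scenario_valves("R2", g2, traces = t2)
  expect_equal(v2$scenario, "R2")
  ## open and closed aortic templates exist and differ
  expect_gt(nrow(vH$aortic_open$tris), 0)
  expect_gt(nrow(vH$aortic_closed$tris), 0)
  expect_false(isTRUE(all.equal(vH$aortic_open$nodes, vH$aortic_closed$nodes)))
  expect_error(make_scenario_valves("R2", g1, traces = t1), "dilation")
})

test_that("trace CSV round-trips", {
  tr <- fix_traces()
  f <- tempfile(fileext = ".csv")
  write_traces_csv(tr, f)
  tr2 <- read_traces_csv(f, center = tr$center)
  expect_equal(tr2$planes[[5L]]$anterior, tr$planes[[5L]]$anterior,
               tolerance = 1e-9, ignore_attr = TRUE)
  cl <- assemble_point_cloud(tr2)
  expect_equal(dim(cl$raw), c(1152L, 3L))
})
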