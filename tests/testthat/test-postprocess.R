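## a tiny box "flow history" with prescribed nodal fields
box_history <- function(u_fun, nx = 5L, p_fun = NULL, steps = 1L) {
  bm <- box_mesh(seq(0, 1e-2, length.out = nx), seq(0, 1e-2, length.out = nx),
                 seq(0, 2e-2, length.out = 2L * nx - 1L))
  n <- nrow(bm$nodes)
  u <- t(apply(bm$nodes, 1L, u_fun))
  p <- if (is.null(p_fun)) numeric(n) else apply(bm$nodes, 1L, p_fun)
  bm$u <- u; bm$p <- p
  bm
}

test_that("slice flow rates follow the sign convention and exact uniform flux", {
  bm <- box_history(function(x) c(0, 0, 2))   # uniform 2 m/s along z
  sl <- plane_slice(c(5e-3, 5e-3, 1e-2), c(0, 0, 1))
  q <- cardioriis:::slice_flux(bm$nodes, bm$tets, bm$u, sl)
  A <- 1e-2 * 1e-2
  expect_equal(q, 2 * A, tolerance = 1e-12)
  ## reversed flow: -U A
  q2 <- cardioriis:::slice_flux(bm$nodes, bm$tets, -bm$u, sl)
  expect_equal(q2, -2 * A, tolerance = 1e-12)
  ## slice outside the mesh fails
  expect_error(cardioriis:::slice_cut(bm$nodes, bm$tets,
                                      plane_slice(c(0, 0, 1), c(0, 0, 1))),
               "does not intersect")
})

test_that("a Poiseuille profile integrates to the closed-form flow rate", {
  pf <- pipe_fixture()
  props <- fluid_properties(rho = 1, mu = 0.1)
  st <- pipe_steady(pf, props, 20)
  sl <- plane_slice(c(0, 0, pf$length / 2), c(0, 0, 1))
  q <- cardioriis:::slice_flux(pf$mesh$nodes, pf$mesh$tets, st$u, sl)
  q_exact <- pi * pf$radius^4 * 20 / (8 * props$mu * pf$length)
  expect_lt(abs(q - q_exact) / q_exact, 0.05)
})

test_that("slice-average pressure is area weighted and exact for linear fields", {
  bm <- box_history(function(x) c(0, 0, 0))
  p <- 1000 + 5e4 * bm$nodes[, 1]   # linear in x
  sl <- plane_slice(c(5e-3, 5e-3, 1e-2), c(0, 0, 1))
  pm <- cardioriis:::slice_average_pressure(bm$nodes, bm$tets, p, sl)
  expect_equal(pm, 1000 + 5e4 * 5e-3, tolerance = 1e-9)
})

test_that("timing features recover constructed peaks and the printed t_dec rule", {
  ## t_v2 = 0.20, t_c = 0.32 -> t_dec = 0.26
  t <- seq(0, 0.32, by = 1e-3)
  q <- 300 * sin(pi * t / 0.32)^2 + 150 * exp(-((t - 0.20) / 0.02)^2)
  tf <- timing_features(t, q, t_c = 0.32)
  expect_equal(tf$t_dec, (tf$t_v2 + 0.32) / 2)
  ## synthetic two-bump curve with known maxima
  q2 <- exp(-((t - 0.08) / 0.03)^2) + 0.8 * exp(-((t - 0.22) / 0.03)^2)
  tf2 <- timing_features(t, q2, t_c = 0.30)
  expect_equal(tf2$t_v1, 0.08, tolerance = 2e-3)
  expect_equal(tf2$t_v2, 0.22, tolerance = 2e-3)
  expect_false(tf2$single_peak)
  expect_equal(tf2$t_dec, (0.22 + 0.30) / 2, tolerance = 2e-3)
  ## monotone flow rate: flagged single-peak path
  tf3 <- timing_features(t, t * 100, t_c = 0.32)
  expect_true(tf3$single_peak)
})

test_that("volume indices reproduce the printed index arithmetic", {
  ## CO = SV x HR: 50 mL at 90 bpm -> 4.5 L/min
  t <- seq(0, 0.26, by = 1e-3)
  q_lvot <- rep(50 / 0.26, length(t))        # integrates to 50 mL
  q_mv <- rep(40 / 0.26, length(t))          # integrates to 40 mL
  idx <- compute_indices(t, q_lvot, q_mv, hr_bpm = 90)
  expect_equal(idx$sv_ml, 50, tolerance = 1e-9)
  expect_equal(idx$rv_ml, 40, tolerance = 1e-9)
  expect_equal(idx$co_l_min, 4.5, tolerance = 1e-9)
  ## RF = RV/(SV+RV): 40/90 -> 44%
  expect_equal(round(idx$rf_pct), 44)
  ## healthy limit: RV = 0 -> RF = 0; negative mitral flow never counts
  idx0 <- compute_indices(t, q_lvot, -q_mv, hr_bpm = 75)
  expect_equal(idx0$rv_ml, 0)
  expect_equal(idx0$rf_pct, 0)
  ## a small RIIS leak below the threshold reports RF = 0
  idxl <- compute_indices(t, q_lvot, rep(1.1 / 0.26, length(t)), hr_bpm = 75)
  expect_equal(idxl$rf_pct, 0)
  expect_gt(idxl$rv_ml, 1)
  expect_error(compute_indices(t, -q_lvot, q_mv, 75), "negative stroke volume")
})

test_that("the mean pressure drop integrates the ejection window correctly", {
  t <- seq(0, 0.32, by = 1e-3)
  pm <- pressure_metrics(t, rep(85, length(t)), rep(80, length(t)),
                         t_o = 0, t_c = 0.32)
  expect_equal(pm$dp_mean, 5, tolerance = 1e-9)
  ## linear ramp 0 -> 10 over the window averages to 5
  pv <- 80 + 10 * t / 0.32
  pm2 <- pressure_metrics(t, pv, rep(80, length(t)), t_o = 0, t_c = 0.32)
  expect_equal(pm2$dp_mean, 5, tolerance = 1e-6)
  ## arbitrary trace against a fine quadrature oracle
  pv3 <- 80 + 20 * sin(2 * pi * t / 0.32)^2
  pm3 <- pressure_metrics(t, pv3, rep(80, length(t)), t_o = 0.05, t_c = 0.30)
  oracle <- integrate(function(x)
    approx(t, pv3 - 80, xout = x)$y, 0.05, 0.30, subdivisions = 2000L)$value / 0.25
  expect_lt(abs(pm3$dp_mean - oracle) / oracle, 1e-3)
  expect_error(pressure_metrics(t, pv, pv, t_o = 0.3, t_c = 0.2), "exceed")
})

test_that("wall shear stress is exact for plane Couette flow", {
  gam <- 150  # shear rate 1/s
  bm <- box_history(function(x) c(gam * x[3], 0, 0))
  bnd <- mesh_boundary(bm$nodes, bm$tets)
  fa <- face_normals_areas(bm$nodes, bnd$faces)
  bottom <- fa$normal[, 3] < -0.99
  mu <- 3.5e-3
  w <- wall_shear_stress(bm$nodes, bm$tets, bm$u, numeric(nrow(bm$tets)), mu,
                         list(type = "wall", faces = bnd$faces[bottom, ],
                              owner = bnd$owner[bottom]))
  expect_equal(max(abs(w$wss - mu * gam)), 0, tolerance = 1e-12)
  ## zero velocity -> zero WSS; histogram counts sum to the sample count
  w0 <- wall_shear_stress(bm$nodes, bm$tets, bm$u * 0, numeric(nrow(bm$tets)), mu,
                          list(type = "wall", faces = bnd$faces[bottom, ],
                               owner = bnd$owner[bottom]))
  expect_equal(max(w0$wss), 0)
  expect_equal(sum(w$hist), length(w$wss))
})

test_that("Poiseuille wall shear matches the closed form within 5%", {
  pf <- pipe_fixture(ns = 4L, nr = 6L)  # wall gradient needs radial resolution
  props <- fluid_properties(rho = 1, mu = 0.1)
  st <- pipe_steady(pf, props, 20)
  bnd <- list(faces = pf$faces[pf$tag == 1L, ], owner = NULL)
  ## owners of the wall faces
  full <- mesh_boundary(pf$mesh$nodes, pf$mesh$tets)
  fa <- face_normals_areas(pf$mesh$nodes, full$faces)
  wallsel <- abs(fa$normal[, 3]) < 0.99
  ## restrict to mid-pipe faces away from the ends
  zc <- fa$centroid[, 3]
  sel <- wallsel & zc > 0.01 & zc < 0.03
  w <- wall_shear_stress(pf$mesh$nodes, pf$mesh$tets, st$u,
                         numeric(nrow(pf$mesh$tets)), props$mu,
                         list(type = "wall", faces = full$faces[sel, ],
                              owner = full$owner[sel]))
  wss_exact <- 20 * pf$radius / (2 * pf$length)   # dp R / (2 L)
  expect_lt(abs(mean(w$wss) - wss_exact) / wss_exact, 0.05)
})

test_that("the turbulence ratio reduces to exact values for constant fields", {
  ## mu_sgs == mu on the mask -> ratio 1; zero -> 0
  dom <- fixture("domain", function() moving_domain(fix_geom(), fix_motion(), dt = 2e-3))
  nsteps <- 3L
  M <- nrow(dom$tets)
  hist <- structure(list(
    times = (1:nsteps) * 1e-3,
    d = array(0, dim = c(nsteps, dom$n, 3L)),
    musgs = matrix(3.5e-3, nsteps, M),
    domain = dom, props = fluid_properties()),
    class = "flow_history")
  tr <- turbulence_ratio(hist)
  expect_equal(tr$r_bar, 1, tolerance = 1e-12)
  hist$musgs <- matrix(0, nsteps, M)
  expect_equal(turbulence_ratio(hist)$r_bar, 0)
  ## spatially varying field against a direct quadrature
  set.seed(1)
  mus <- matrix(runif(M) * 1e-2, nsteps, M, byrow = TRUE)
  hist$musgs <- mus
  v <- tet_volumes(dom$nodes0, dom$tets)
  mask <- dom$region == 2L
  oracle <- sum(mus[1L, mask] * v[mask]) / sum(v[mask]) / 3.5e-3
  expect_equal(turbulence_ratio(hist)$r_bar, oracle, tolerance = 1e-9)
  expect_error(turbulence_ratio(hist, mask = integer(0)), "empty")
})
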