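test_that("the sigma-model viscosity vanishes for canonical laminar states", {
  les <- les_params(C = 1.5, delta = 1.5e-3)
  rho <- 1.06e3
  shear <- matrix(c(0, 3, 0, 0, 0, 0, 0, 0, 0), 3L, 3L, byrow = TRUE)
  expect_equal(sigma_viscosity(shear, les, rho), 0)
  rot <- matrix(c(0, -2, 0, 2, 0, 0, 0, 0, 0), 3L, 3L, byrow = TRUE)
  expect_equal(sigma_viscosity(rot, les, rho), 0)
  expect_equal(sigma_viscosity(matrix(0, 3L, 3L), les, rho), 0)  # zero gradient
  ## uniform-in-space velocity on a mesh gives mu_sgs == 0 everywhere
  bm <- box_mesh(seq(0, 1e-2, length.out = 4L), seq(0, 1e-2, length.out = 4L),
                 seq(0, 1e-2, length.out = 4L))
  uuni <- matrix(rep(c(0.3, -0.1, 0.2), each = nrow(bm$nodes)), ncol = 3L)
  cg <- cardioriis:::cpp_cell_gradients(bm$nodes, bm$tets, uuni)
  expect_equal(max(cardioriis:::musgs_from_sv(cg$sv, les$C, les$delta, rho)), 0)
})

test_that("a diagonal gradient matches the SVD oracle to 1e-12 relative", {
  les <- les_params(C = 1.5, delta = 1.5e-3)
  rho <- 1.06e3
  g <- diag(c(3, 2, 1))
  got <- sigma_viscosity(g, les, rho)
  sv <- svd(g)$d   # independent oracle
  expected <- rho * les$C * les$delta^2 * sv[3] * (sv[1] - sv[2]) * (sv[2] - sv[3]) / sv[1]^2
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(got, rho * les$C * les$delta^2 / 9, tolerance = 1e-12)
  ## random gradients against the oracle, always non-negative
  set.seed(5)
  for (k in 1:20) {
    gr <- matrix(rnorm(9), 3L, 3L)
    sv <- svd(gr)$d
    expected <- rho * les$C * les$delta^2 * sv[3] * (sv[1] - sv[2]) * (sv[2] - sv[3]) / sv[1]^2
    expect_equal(sigma_viscosity(gr, les, rho), max(expected, 0), tolerance = 1e-10)
    expect_gte(sigma_viscosity(gr, les, rho), 0)
  }
})

test_that("zero forcing and zero initial state stay exactly zero", {
  bm <- box_mesh(seq(0, 1e-2, length.out = 4L), seq(0, 1e-2, length.out = 4L),
                 seq(0, 2e-2, length.out = 6L))
  bnd <- mesh_boundary(bm$nodes, bm$tets)
  allb <- unique(as.integer(bnd$faces))
  u <- matrix(0, nrow(bm$nodes), 3L)
  p <- numeric(nrow(bm$nodes))
  for (s in 1:3) {
    r <- ns_step(bm$nodes, bm$tets, u, u * 0, fluid_properties(), dt = 1e-3,
                 wall_nodes = allb, p_old = p)
    u <- r$u; p <- r$p
  }
  expect_equal(max(abs(u)), 0)
  expect_equal(max(abs(p)), 0)
})

test_that("the stabilized scheme recovers Poiseuille pipe flow within 5%", {
  pf <- pipe_fixture()
  props <- fluid_properties(rho = 1, mu = 0.1)   # creeping-flow verification
  dp <- 20
  st <- pipe_steady(pf, props, dp)
  rr <- sqrt(pf$mesh$nodes[, 1]^2 + pf$mesh$nodes[, 2]^2)
  mid <- which(abs(pf$mesh$nodes[, 3] - pf$length / 2) < 1e-9 & rr < 1e-9)
  u_exact <- dp * pf$radius^2 / (4 * props$mu * pf$length)
  expect_lt(abs(st$u[mid, 3] - u_exact) / u_exact, 0.05)
  ## flow rate against the closed form
  q_exact <- pi * pf$radius^4 * dp / (8 * props$mu * pf$length)
  expect_lt(abs(st$flux_out - q_exact) / q_exact, 0.05)
})

test_that("a closed RIIS membrane blocks the channel and tightens with R", {
  pf <- pipe_fixture(extra_z = 20e-3 + c(-2e-3, -1e-3, -5e-4, 5e-4, 1e-3, 2e-3))
  props <- fluid_properties(rho = 1, mu = 3.5e-3)
  mem <- disc_membrane(pf$radius, pf$length / 2)
  open_q <- pipe_steady(pf, props, 20)$flux_out
  eps <- 7.5e-4
  ratios <- vapply(c(1e2, 1e3, 1e4), function(R) {
    dd <- distance_and_delta(mem$nodes, mem$tris, pf$mesh$nodes, eps)
    st <- pipe_steady(pf, props, 20, riis_node = R / eps * dd$delta)
    st$flux_out / open_q
  }, numeric(1))
  expect_lt(ratios[3L], 0.01)           # R = 1e4: < 1% of the open flux
  expect_true(all(diff(ratios) < 0))    # monotone in R
  expect_true(all(ratios > 0))
})

test_that("velocity mismatch on the delta layer decreases monotonically with R", {
  pf <- pipe_fixture(extra_z = 20e-3 + c(-1e-3, 1e-3))
  props <- fluid_properties(rho = 1, mu = 3.5e-3)
  mem <- disc_membrane(pf$radius, pf$length / 2)
  eps <- 7.5e-4
  dd <- distance_and_delta(mem$nodes, mem$tris, pf$mesh$nodes, eps)
  layer <- dd$delta > 0
  mism <- vapply(c(1e2, 1e3, 1e4), function(R) {
    st <- pipe_steady(pf, props, 20, riis_node = R / eps * dd$delta)
    sqrt(mean(rowSums(st$u[layer, , drop = FALSE]^2)))
  }, numeric(1))
  expect_true(all(diff(mism) < 0))
})

test_that("null-tangential backflow control annihilates tangential outlet velocity", {
  pf <- pipe_fixture()
  props <- fluid_properties(rho = 1, mu = 0.1)
  out_nodes <- setdiff(unique(as.integer(pf$faces[pf$tag == 3L, ])), pf$wall_nodes)
  bfc <- apply_backflow_control(pf$mesh$nodes, pf$faces[pf$tag == 3L, ],
                                out_nodes, "null_tangential")
  outs <- list(list(faces = pf$faces[pf$tag == 2L, ], p_pa = 20),
               list(faces = pf$faces[pf$tag == 3L, ], p_pa = 0))
  st <- ns_steady(pf$mesh$nodes, pf$mesh$tets, props, wall_nodes = pf$wall_nodes,
                  outlets = outs, extra_dirichlet = bfc)
  tang <- sqrt(st$u[out_nodes, 1L]^2 + st$u[out_nodes, 2L]^2)
  expect_lt(max(tang), 1e-10 * max(abs(st$u)))
  ## away from the constrained outlet the solution is unchanged
  st0 <- ns_steady(pf$mesh$nodes, pf$mesh$tets, props, wall_nodes = pf$wall_nodes,
                   outlets = outs)
  midsel <- pf$mesh$nodes[, 3] < 0.6 * pf$length
  expect_lt(max(abs(st$u[midsel, ] - st0$u[midsel, ])) / max(abs(st0$u)), 0.01)
  expect_null(apply_backflow_control(pf$mesh$nodes, pf$faces[pf$tag == 3L, ],
                                     out_nodes, "none"))
})

test_that("kinetic energy decays under zero forcing with fixed walls", {
  pf <- pipe_fixture(nz = 9L)
  props <- fluid_properties(rho = 1, mu = 0.1)
  ## start from a driven state, then free decay with all boundaries no-slip
  st <- pipe_steady(pf, props, 20)
  allb <- unique(as.integer(pf$faces))
  u <- st$u; u[allb, ] <- 0
  p <- st$p
  ke <- function(u) sum(rowSums(u^2))
  k_prev <- ke(u)
  for (s in 1:5) {
    r <- ns_step(pf$mesh$nodes, pf$mesh$tets, u, u * 0, props, dt = 1e-3,
                 wall_nodes = allb, p_old = p)
    u <- r$u; p <- r$p
    expect_lte(ke(u), k_prev + 1e-12)
    k_prev <- ke(u)
  }
})

test_that("the aortic valve controller follows the opening and closing rules", {
  ## healthy: initialized open with t_o = 0
  cH <- aortic_valve_controller("open", t0 = 0)
  expect_equal(cH$state, "open")
  expect_equal(cH$t_open, 0)
  ## synthetic pressures crossing at step k -> opening at exactly k dt
  ctrl <- aortic_valve_controller("closed")
  dt <- 1e-3
  p_vent <- c(40, 60, 79, 81, 100) * 133.322
  p_ao <- rep(80, 5) * 133.322
  for (k in 1:5)
    ctrl <- update_aortic_valve(ctrl, p_vent[k], p_ao[k], q_aortic = 1e-4, t = k * dt)
  expect_equal(ctrl$t_open, 4 * dt)
  ## closing at the first negative flow after forward ejection
  q <- c(1e-4, 5e-5, -2e-5, -1e-4)
  for (m in 1:4)
    ctrl <- update_aortic_valve(ctrl, 90 * 133.322, 80 * 133.322, q[m], t = (5 + m) * dt)
  expect_equal(ctrl$state, "closed")
  expect_equal(ctrl$t_close, 8 * dt)
  ## re-opening is rejected and logged (single-cycle contract)
  ctrl <- update_aortic_valve(ctrl, 120 * 133.322, 80 * 133.322, 0, t = 10 * dt)
  expect_equal(ctrl$state, "closed")
  expect_true(any(grepl("rejected", ctrl$log)))
})
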