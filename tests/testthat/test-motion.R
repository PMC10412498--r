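domain_fixture <- function() fixture("domain", function()
  moving_domain(fix_geom(), fix_motion(), dt = 2e-3))

test_that("time interpolation passes through the frames and reproduces cubics", {
  dom <- domain_fixture()
  for (i in c(1L, 3L, 6L)) {
    d <- interp_displacement(dom, dom$times[i])
    expect_equal(d, dom$frames[[i]], tolerance = 1e-10)
  }
  expect_error(interp_displacement(dom, -0.01), "outside")
  expect_error(interp_displacement(dom, dom$t_end + 0.01), "outside")
  ## frames sampled from a cubic polynomial in t are recovered exactly
  ## between knots (cubic-spline reproduction)
  dom2 <- dom
  poly <- function(t) 1 + 2 * t - 3 * t^2 + 4 * t^3
  dom2$frames <- lapply(dom$times, function(t)
    matrix(poly(t), dom$n, 3L))
  for (t in c(0.031, 0.155, 0.27)) {
    d <- interp_displacement(dom2, t)
    expect_equal(d[1L, 1L], poly(t), tolerance = 1e-10)
  }
  ## all-zero frames interpolate to zero
  dom3 <- dom
  dom3$frames <- lapply(dom$frames, function(f) f * 0)
  expect_equal(max(abs(interp_displacement(dom3, 0.123))), 0)
})

test_that("the elastic extension satisfies its boundary conditions and a dense oracle", {
  dom <- domain_fixture()
  ## zero boundary data -> zero field
  z <- extend_harmonic(dom, matrix(0, dom$n, 3L))
  expect_equal(max(abs(z)), 0)
  ## atrial outlet stays exactly fixed for real data
  d <- extend_harmonic(dom, dom$frames[[1L]])
  expect_equal(max(abs(d[dom$sig1, ])), 0)
  expect_equal(d[dom$wall, ], dom$frames[[1L]][dom$wall, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  ## dense direct solve on the same coarse system agrees
  Kd <- as.matrix(dom$K)
  fixed <- dom$fixed
  free <- dom$free
  xall <- numeric(3L * dom$n)
  xc <- matrix(0, dom$n, 3L)
  xc[dom$wall, ] <- dom$frames[[1L]][dom$wall, ]
  xfix <- c(xc[c(dom$wall, dom$sig1), 1L], xc[c(dom$wall, dom$sig1), 2L],
            xc[c(dom$wall, dom$sig1), 3L])
  xall[fixed] <- xfix
  xall[free] <- solve(Kd[free, free], -Kd[free, fixed] %*% xfix)
  dense <- matrix(xall, dom$n, 3L)
  expect_lt(max(abs(dense - d)) / max(abs(d)), 1e-8)
  ## residual of the free equations
  res <- Kd[free, , drop = FALSE] %*% as.numeric(d)
  expect_lt(max(abs(res)) / max(abs(Kd %*% as.numeric(d))), 1e-9)
})

test_that("ALE and wall velocities are exact difference quotients", {
  dom <- domain_fixture()
  n <- dom$n
  d1 <- matrix(rnorm(3 * n), n, 3L) * 1e-4
  d0 <- matrix(rnorm(3 * n), n, 3L) * 1e-4
  v <- ale_velocities(d1, d0, d1, d0, dt = 2.5e-4, wall = dom$wall)
  expect_equal(v$u_ale, (d1 - d0) / 2.5e-4, tolerance = 1e-14)
  expect_equal(max(abs(v$u_wall[-dom$wall, ])), 0)
  ## equal successive displacements -> zero velocities
  v0 <- ale_velocities(d1, d1, d1, d1, dt = 1e-3)
  expect_equal(max(abs(v0$u_ale)), 0)
  ## linear-in-time displacement -> exact constant velocity
  cvec <- c(1e-3, -2e-3, 5e-4)
  da <- outer(rep(1, n), cvec) * 0.1
  db <- outer(rep(1, n), cvec) * 0.2
  vl <- ale_velocities(db, da, db, da, dt = 0.1)
  expect_equal(vl$u_ale, outer(rep(1, n), cvec), tolerance = 1e-12)
  expect_error(ale_velocities(d1, d0, d1, d0, dt = 0), "positive")
})

test_that("the moved mesh stays valid over a full systole and volume flux is consistent", {
  dom <- domain_fixture()
  times <- seq(0, dom$t_end, length.out = 21L)
  vols <- numeric(length(times))
  for (k in seq_along(times)) {
    d <- cardioriis:::interp_volume_displacement(dom, times[k])
    v <- tet_volumes(dom$nodes0 + d, dom$tets)
    expect_gt(min(v), 0)
    vols[k] <- surface_enclosed_volume(dom$nodes0 + d, dom$faces)
  }
  ## geometric conservation sanity: volume change per interval matches the
  ## surface flux of the wall velocity to first order in dt
  k <- 11L
  dtk <- times[k + 1L] - times[k]
  d0 <- cardioriis:::interp_volume_displacement(dom, times[k])
  d1 <- cardioriis:::interp_volume_displacement(dom, times[k + 1L])
  umesh <- (d1 - d0) / dtk
  midnodes <- dom$nodes0 + (d0 + d1) / 2
  flux <- boundary_flux(midnodes, umesh, dom$faces)
  expect_lt(abs(flux - (vols[k + 1L] - vols[k]) / dtk) /
              max(abs(flux), 1e-12), 0.05)
})
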