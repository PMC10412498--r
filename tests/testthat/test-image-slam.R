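test_that("the distance weight peaks at zero, decreases, and has compact support", {
  cfg <- slam_config(scale_mm = 4, cutoff_mm = 12)
  expect_equal(slam_weight(0, cfg), 1)
  expect_equal(slam_weight(4, cfg), exp(-1 / 2))
  d <- seq(0, 20, by = 0.5)
  w <- slam_weight(d, cfg)
  expect_true(all(diff(w) <= 0))
  expect_true(all(w[d > 12] == 0))
  expect_true(all(w >= 0))
})

## build a tiny synthetic anisotropic stack sampled from a field f(x,y,z)
synth_series <- function(f, nx = 9L, ny = 9L, nz = 4L, dz = 8) {
  arr <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx))
    arr[i, j, k] <- f(i - 1, j - 1, (k - 1) * dz)
  voxel_series(list(arr), spacing = c(1, 1, dz), origin = c(0, 0, 0),
               times = 0)
}

test_that("merging reproduces source values exactly at coincident voxels", {
  f <- function(x, y, z) 3.7
  sax <- synth_series(f)
  out <- slam_merge(sax, list(), slam_config())
  ## every output voxel is a convex combination of identical values
  expect_equal(max(abs(out$frames[[1L]] - 3.7)), 0, tolerance = 1e-12)
})

test_that("a globally affine intensity field is reproduced at mid-slice voxels", {
  f <- function(x, y, z) 2 + 0.5 * x - 0.25 * y + 0.125 * z
  sax <- synth_series(f)
  out <- slam_merge(sax, list(), slam_config())
  ## affine fields are preserved only where the contributing slices lie
  ## symmetrically: z = 12 sees slices at 8 and 16 (distance 4) and at 0 and
  ## 24 (distance 12), both pairs symmetric about it
  arr <- out$frames[[1L]]
  k12 <- 13L  # 1 mm spacing: z index 13 -> z = 12
  for (i in c(2L, 5L, 8L)) for (j in c(2L, 5L, 8L)) {
    expect_equal(arr[i, j, k12], f(i - 1, j - 1, 12), tolerance = 1e-9)
  }
})

test_that("merged intensities stay within the source range (convexity)", {
  set.seed(42)
  arr <- array(runif(9 * 9 * 4), dim = c(9, 9, 4))
  sax <- voxel_series(list(arr), spacing = c(1, 1, 8), origin = c(0, 0, 0), times = 0)
  out <- slam_merge(sax, list(), slam_config())
  expect_gte(min(out$frames[[1L]][!attr(out, "background")]), min(arr))
  expect_lte(max(out$frames[[1L]]), max(arr))
})

test_that("already-isotropic consistent input is reproduced at coincident voxels", {
  f <- function(x, y, z) 1 + 0.1 * x + 0.2 * y + 0.05 * z
  arr <- array(0, dim = c(7, 7, 7))
  for (k in 1:7) for (j in 1:7) for (i in 1:7) arr[i, j, k] <- f(i - 1, j - 1, k - 1)
  iso <- voxel_series(list(arr), spacing = c(1, 1, 1), origin = c(0, 0, 0), times = 0)
  out <- slam_merge(iso, list(), slam_config())
  expect_equal(out$frames[[1L]][2:6, 2:6, 2:6], arr[2:6, 2:6, 2:6], tolerance = 1e-6)
})

test_that("SLAM beats nearest-slice replication on the phantom (cross-slice RMS)", {
  spec <- fix_spec(); g <- fix_geom(); m <- fix_motion()
  plan <- list(sax_n = 6L, sax_spacing_mm = 8, inplane_mm = 2, frames = 6L,
               subsamp = c(2L, 2L, 3L))
  img <- render_image_series(spec, g, m, slice_plan = plan)
  merged <- slam_merge(img$sax, img$lax, slam_config(spacing_mm = 2))
  repl <- nearest_slice_replication(img$sax, spacing_mm = 2)
  ## ground truth rendered directly at the isotropic grid
  fine <- render_image_series(spec, g, m,
                              slice_plan = list(sax_n = (6L - 1L) * 4L + 1L,
                                                sax_spacing_mm = 2, inplane_mm = 2,
                                                frames = 6L, subsamp = c(2L, 2L, 3L),
                                                thickness_mm = 2))
  nz <- min(dim(merged$frames[[1L]])[3], dim(fine$sax$frames[[1L]])[3],
            dim(repl$frames[[1L]])[3])
  truth <- fine$sax$frames[[1L]][, , seq_len(nz)]
  rms <- function(a) sqrt(mean((a[, , seq_len(nz)] - truth)^2))
  expect_lt(rms(merged$frames[[1L]]), rms(repl$frames[[1L]]))
})
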