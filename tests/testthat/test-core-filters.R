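test_that("TIFF stack round trip is lossless for integer data", {
  set.seed(101)
  arr <- array(sample.int(65536L, 10 * 12 * 9, replace = TRUE) - 1L, c(10, 12, 9))
  g <- voxel_grid(arr, voxel_size = c(3, 0.7, 0.7), channel = "nuclei")
  f <- withr::local_tempfile(fileext = ".tif")
  write_stack(g, f, bits = 16L)
  g2 <- read_stack(f, voxel_size = c(3, 0.7, 0.7), channel = "nuclei")
  expect_identical(dim(g2$data), c(10L, 12L, 9L))
  expect_true(all(g2$data == arr))
  expect_equal(g2$voxel_size, c(3, 0.7, 0.7))

  # single page keeps a z-dimension of one
  g1 <- voxel_grid(array(c(0L, 1L, 2L, 3L), c(1, 2, 2)))
  f1 <- withr::local_tempfile(fileext = ".tif")
  write_stack(g1, f1, bits = 8L)
  r1 <- read_stack(f1)
  expect_identical(dim(r1$data), c(1L, 2L, 2L))
  expect_true(all(r1$data == g1$data))

  expect_error(read_stack(file.path(tempdir(), "no-such-file.tif")), "not found")
})

test_that("voxel grid containers validate their invariants", {
  expect_error(voxel_grid(matrix(0, 2, 2)), "3D")
  expect_error(voxel_grid(array(-1, c(2, 2, 2))), ">= 0")
  expect_error(voxel_grid(array(Inf, c(2, 2, 2))), "finite")
  expect_error(voxel_grid(array(0, c(2, 2, 2)), voxel_size = c(0, 1, 1)), "positive")
  expect_error(binary_volume(array(NA, c(2, 2, 2))), "NA")
})

test_that("sub-volume tiling is centred, disjoint and sub-arrays of the input", {
  set.seed(7)
  # >= 1.85 mm wide grid at 0.7 um/px, tiles of 0.37 x 0.37 mm
  nx <- 5L * round(370 / 0.7) + 2L
  g <- voxel_grid(array(runif(4 * 560 * nx), c(4, 560, nx)), c(3, 0.7, 0.7))
  tiles <- extract_subvolumes(g, 5L, c(370, 370))
  expect_length(tiles, 5L)
  tx <- as.integer(round(370 / 0.7))
  for (t in tiles) expect_identical(dim(t$data), c(4L, tx, tx))
  # contiguous along x, so total footprint is 5 x 370 um = 1.85 mm
  orgs <- t(vapply(tiles, attr, integer(3), "origin"))
  expect_equal(diff(orgs[, "x"]), rep(tx, 4))
  # each tile is the corresponding sub-array of the input
  o <- orgs[3, ]
  expect_identical(tiles[[3]]$data,
                   g$data[, o["y"]:(o["y"] + tx - 1), o["x"]:(o["x"] + tx - 1), drop = FALSE])

  # identity case: one tile covering the full extent
  g2 <- voxel_grid(array(runif(3 * 8 * 8), c(3, 8, 8)), c(1, 1, 1))
  t2 <- extract_subvolumes(g2, 1L, c(8, 8))
  expect_identical(t2[[1]]$data, g2$data)

  expect_error(extract_subvolumes(g2, 3L, c(8, 8)), "exceeds")
})

test_that("plane-wise median filter matches the brute-force window oracle", {
  # constants are invariant
  g <- grid3(array(5, c(3, 6, 6)))
  expect_equal(median_filter_xy(g, 1L)$data, g$data)
  # an isolated impulse is rejected
  a <- array(0, c(1, 5, 5)); a[1, 3, 3] <- 100
  expect_true(all(median_filter_xy(grid3(a), 1L)$data == 0))
  # seeded plane equals the per-pixel sorted-window oracle
  set.seed(11)
  m <- matrix(runif(49), 7, 7)
  g <- grid3(array(m, c(1, 7, 7)))
  expect_equal(median_filter_xy(g, 1L)$data[1, , ], median_oracle(m, 1L))
  expect_equal(median_filter_xy(g, 2L)$data[1, , ], median_oracle(m, 2L))
  # planes are filtered independently: no cross-plane mixing
  a2 <- array(0, c(2, 5, 5)); a2[2, , ] <- 1
  expect_equal(median_filter_xy(grid3(a2), 1L)$data, a2)
})

test_that("linear rescaling maps percentiles to [0, 1] and flags degenerate input", {
  set.seed(12)
  g <- grid3(array(runif(4000, 2, 7), c(10, 20, 20)))
  r <- rescale_linear(g)
  expect_equal(max(r$data), 1)
  expect_equal(min(r$data), 0)
  expect_warning(z <- rescale_linear(grid3(array(3, c(2, 4, 4)))), "degenerate")
  expect_true(all(z$data == 0))
  # percentile clipping touches about the expected tail mass
  r2 <- rescale_linear(g, 1, 99)
  clipped <- mean(r2$data == 0 | r2$data == 1)
  expect_lte(clipped, 0.025)
  expect_gte(clipped, 0.01)
})

test_that("rolling-ball subtraction removes broad background and keeps small features", {
  # a constant plane is pure background
  g <- grid3(array(4, c(2, 20, 20)))
  expect_true(all(rolling_ball_xy(g, 5L)$data == 0))
  # a small bright disk (diameter < ball radius) survives nearly intact:
  # the ball can only penetrate the gap by R - sqrt(R^2 - (w/2)^2)
  a <- array(0, c(1, 31, 31))
  for (y in 1:31) for (x in 1:31)
    if ((y - 16)^2 + (x - 16)^2 <= 9) a[1, y, x] <- 10
  out <- rolling_ball_xy(grid3(a), 10L)
  expect_gte(mean(out$data[a > 0]), 0.8 * 10)
  expect_true(all(out$data[1, 1:5, 1:5] == 0))
  # a linear ramp is flattened: residual strictly below the ramp amplitude
  ramp <- array(rep(seq(0, 5, length.out = 40), each = 1), c(1, 1, 40))
  ramp <- grid3(array(rep(ramp, 30), c(1, 30, 40)))
  res <- rolling_ball_xy(ramp, 8L)
  expect_lt(max(res$data), 5)
  # pointwise bounds hold on arbitrary volumes (large radius takes the
  # downscaled path)
  set.seed(13)
  g3 <- grid3(array(runif(20 * 64 * 64), c(20, 64, 64)))
  for (r in c(6L, 24L)) {
    o <- rolling_ball_xy(g3, r)
    expect_true(all(o$data >= 0))
    expect_true(all(o$data <= g3$data + 1e-12))
  }
})

test_that("hysteresis keeps weak voxels only when linked to strong seeds", {
  # hand-checked 1D chain
  chain <- grid3(array(c(0.2, 0.6, 0.9, 0.6, 0.2), c(1, 1, 5)))
  m <- hysteresis_threshold(chain, 0.5, 0.8)
  expect_equal(as.vector(m$mask), c(FALSE, TRUE, TRUE, TRUE, FALSE))
  # no signal -> empty (thresholds are fractions of the max, so only a
  # zero volume has no seeds); all voxels at the max -> full
  expect_false(any(hysteresis_threshold(grid3(array(0, c(1, 1, 2))), 0.5, 0.99)$mask))
  expect_true(all(hysteresis_threshold(grid3(array(1, c(2, 2, 2))), 0.2, 0.5)$mask))
  # sandwich property on seeded random volumes
  set.seed(14)
  for (i in 1:5) {
    g <- grid3(array(runif(6 * 9 * 9), c(6, 9, 9)))
    hy <- hysteresis_threshold(g, 0.3, 0.7)$mask
    hi <- g$data >= 0.7 * max(g$data)
    lo <- g$data >= 0.3 * max(g$data)
    expect_true(all(hy[hi]))       # high-threshold mask is contained
    expect_true(all(lo[hy]))       # result is contained in low-threshold mask
  }
  expect_error(hysteresis_threshold(grid3(array(1, c(1, 1, 2))), 0.8, 0.5), "low")
})

test_that("disk closing/opening fills holes, removes specks, and radius 0 is identity", {
  a <- array(FALSE, c(1, 15, 15)); a[1, 4:12, 4:12] <- TRUE
  hole <- a; hole[1, 8, 8] <- FALSE
  m <- morph_close_open(binary_volume(hole, c(1, 1, 1)), 2L)
  expect_true(m$mask[1, 8, 8])
  speck <- array(FALSE, c(1, 15, 15)); speck[1, 8, 8] <- TRUE
  m2 <- morph_close_open(binary_volume(speck, c(1, 1, 1)), 2L)
  expect_false(any(m2$mask))
  b <- binary_volume(a, c(1, 1, 1))
  expect_identical(morph_close_open(b, 0L)$mask, b$mask)
})

test_that("volume fraction is a plain voxel-count ratio, axis-permutation invariant", {
  m <- array(FALSE, c(4, 4, 4)); m[1:2, 1:2, 1:2] <- TRUE
  expect_equal(volume_fraction(binary_volume(m, c(1, 1, 1))), 0.125)
  expect_equal(volume_fraction(binary_volume(array(FALSE, c(2, 2, 2)), c(1, 1, 1))), 0)
  expect_equal(volume_fraction(binary_volume(array(TRUE, c(2, 2, 2)), c(1, 1, 1))), 1)
  set.seed(15)
  r <- array(runif(3 * 4 * 5) < 0.3, c(3, 4, 5))
  vf <- volume_fraction(binary_volume(r, c(1, 1, 1)))
  expect_equal(vf, sum(r) / length(r))
  expect_equal(volume_fraction(binary_volume(aperm(r, c(2, 3, 1)), c(1, 1, 1))), vf)
})
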