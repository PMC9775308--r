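test_that("generators are pure functions of (spec, seed)", {
  sp <- phantom_spec(shape_vox = c(16L, 24L, 24L), seed = 61L,
                     epidermis = list(mean_thickness_um = 21, sd_um = 3,
                                      surface_roughness_um = 5),
                     droplets = list(n = 4L, radius_range_um = c(4, 6),
                                     layer_z_range_um = c(10, 45)))
  a <- make_epidermis_phantom(sp); b <- make_epidermis_phantom(sp)
  expect_identical(a$k10$data, b$k10$data)
  expect_identical(a$nuclei$data, b$nuclei$data)
  da <- make_adipose_phantom(sp); db <- make_adipose_phantom(sp)
  expect_identical(da$bodipy$data, db$bodipy$data)
  g <- grid3(array(0, c(10, 10, 10)))
  n1 <- apply_noise(g, list(gaussian_sd = 0.1, background_ramp_amplitude = 0.2,
                            autofluor_blob_density = 50), seed = 62L)
  n2 <- apply_noise(g, list(gaussian_sd = 0.1, background_ramp_amplitude = 0.2,
                            autofluor_blob_density = 50), seed = 62L)
  expect_identical(n1$data, n2$data)
})

test_that("epidermal slab geometry matches its stated statistics", {
  # deterministic slab: 30 um at dz = 3 is exactly 10 planes per column
  sp <- phantom_spec(shape_vox = c(16L, 20L, 20L), voxel_size = c(3, 0.7, 0.7),
                     epidermis = list(mean_thickness_um = 30, sd_um = 0,
                                      surface_roughness_um = 0), seed = 63L)
  ph <- make_epidermis_phantom(sp)
  expect_true(all(ph$truth$z_top - ph$truth$z_bottom + 1L == 10L))
  expect_true(all(ph$truth$thickness_um == 30))
  # truth extents agree with the rasterized mask
  tm <- thickness_map(ph$truth$mask)
  expect_equal(tm$thickness_um, ph$truth$thickness_um)
  # stochastic field: empirical mean within 1 um of target at 10^4 columns
  sp2 <- phantom_spec(shape_vox = c(45L, 100L, 100L), voxel_size = c(3, 0.7, 0.7),
                      epidermis = list(mean_thickness_um = 90, sd_um = 5,
                                       surface_roughness_um = 10), seed = 64L)
  ph2 <- make_epidermis_phantom(sp2)
  expect_lte(abs(mean(ph2$truth$thickness_um) - 90), 1)
  # slab thicker than the volume is rejected
  expect_error(make_epidermis_phantom(
    phantom_spec(shape_vox = c(5L, 8L, 8L), voxel_size = c(3, 1, 1),
                 epidermis = list(mean_thickness_um = 60, sd_um = 0))),
    "thicker")
})

test_that("tube rasterization matches analytic capsule volume", {
  # one axis-aligned tube r = 5 um in an isotropic 1 um grid
  sp <- phantom_spec(shape_vox = c(24L, 24L, 40L), voxel_size = c(1, 1, 1),
                     vessels = list(list(control_points = rbind(c(12, 12, -10),
                                                                c(12, 12, 50)),
                                         radius_um = 5)))
  vp <- make_vessel_phantom(sp)
  vox_vol <- sum(vp$truth$mask$mask)          # um^3 at unit voxels
  expect_lte(abs(vox_vol / (pi * 25 * 40) - 1), 0.05)
  # truth VF comes from the same rasterization as the mask
  expect_equal(volume_fraction(vp$truth$mask), vp$truth$vf)
  # zero tubes: empty channel and truth
  v0 <- make_vessel_phantom(phantom_spec(shape_vox = c(8L, 8L, 8L)))
  expect_equal(v0$truth$vf, 0)
  expect_true(all(v0$col4$data == 0))
  # unresolvable radius warns
  expect_warning(make_vessel_phantom(
    phantom_spec(shape_vox = c(8L, 8L, 8L), voxel_size = c(3, 1, 1),
                 vessels = list(list(control_points = rbind(c(4, 4, 0), c(4, 4, 8)),
                                     radius_um = 1)))),
    "unresolvable")
})

test_that("droplet rasterization matches analytic sphere volume and scales with intensity", {
  sp <- phantom_spec(shape_vox = c(30L, 30L, 30L), voxel_size = c(1, 1, 1),
                     droplets = list(n = 1L, radius_range_um = c(10, 10),
                                     layer_z_range_um = c(0, 30)), seed = 65L)
  ad <- make_adipose_phantom(sp)
  expect_lte(abs(sum(ad$truth$mask$mask) / 4189 - 1), 0.05)
  # halved intensity, same seed: identical geometry, half the raw sum
  sp2 <- phantom_spec(shape_vox = sp$shape_vox, voxel_size = sp$voxel_size,
                      droplets = utils::modifyList(sp$droplets, list(intensity = 0.5)),
                      seed = 65L)
  ad2 <- make_adipose_phantom(sp2)
  expect_identical(ad2$truth$mask$mask, ad$truth$mask$mask)
  expect_equal(sum(ad2$bodipy$data), 0.5 * sum(ad$bodipy$data))
  # no droplets: zero channel
  a0 <- make_adipose_phantom(phantom_spec(shape_vox = c(8L, 8L, 8L),
                                          droplets = list(n = 0L)))
  expect_true(all(a0$bodipy$data == 0))
  # droplets that cannot fit are rejected after bounded retries
  expect_error(make_adipose_phantom(
    phantom_spec(shape_vox = c(10L, 10L, 10L), voxel_size = c(1, 1, 1),
                 droplets = list(n = 50L, radius_range_um = c(4, 4),
                                 layer_z_range_um = c(0, 10)))),
    "non-overlapping")
})

test_that("noise model is seeded, additive and moment-correct", {
  g <- grid3(array(1, c(6, 6, 6)))
  expect_identical(apply_noise(g, list(), 1L)$data, g$data)  # all-zero spec
  # clipped-Gaussian SD on an empty background, corrected for clipping
  g0 <- grid3(array(0, c(100L, 100L, 100L)))
  gn <- apply_noise(g0, list(gaussian_sd = 0.2), seed = 66L)
  corr <- sqrt(1 / 2 - 1 / (2 * pi))
  expect_lte(abs(sd(gn$data) / corr / 0.2 - 1), 0.02)
  expect_true(all(gn$data >= 0))
  # ramp and blobs only add intensity
  gr <- apply_noise(g, list(background_ramp_amplitude = 0.3,
                            autofluor_blob_density = 100), seed = 67L)
  expect_true(all(gr$data >= g$data - 1e-12))
  expect_error(apply_noise(g, list(gaussian_sd = -1), 1L), ">= 0")
})

test_that("production distance transform agrees with the exhaustive oracle", {
  set.seed(68)
  vs_list <- list(c(1, 1, 1), c(3, 0.7, 0.7))
  for (i in 1:10) {
    d <- c(sample(6:16, 1), sample(6:16, 1), sample(6:16, 1))
    m <- array(runif(prod(d)) < 0.06, d)
    if (!any(m)) m[1, 1, 1] <- TRUE
    for (vs in vs_list) {
      bv <- binary_volume(m, vs)
      expect_lt(abs(diffusion_length(bv) - brute_force_rk(bv)), 1e-9)
    }
  }
  # single vessel voxel in the centre of a 21^3 isotropic grid
  m <- array(FALSE, c(21, 21, 21)); m[11, 11, 11] <- TRUE
  bv <- binary_volume(m, c(1, 1, 1))
  expect_equal(diffusion_length(bv), brute_force_rk(bv))
  # anisotropic plane source
  pl <- array(FALSE, c(20, 6, 6)); pl[1, , ] <- TRUE
  bp <- binary_volume(pl, c(3, 0.7, 0.7))
  expect_equal(diffusion_length(bp), brute_force_rk(bp))
  expect_equal(brute_force_rk(binary_volume(array(TRUE, c(3, 3, 3)), c(1, 1, 1))), 0)
  expect_error(brute_force_rk(binary_volume(array(TRUE, c(50, 50, 50)), c(1, 1, 1))),
               "too large")
})

test_that("diffusion length grows with tube spacing", {
  rks <- vapply(c(20, 40, 80), function(s) {
    sp <- phantom_spec(shape_vox = c(40L, 40L, 40L), voxel_size = c(2, 2, 2),
                       vessels = parallel_tubes(c(40L, 40L, 40L), c(2, 2, 2),
                                                spacing_um = s, radius_um = 5))
    vp <- make_vessel_phantom(sp)
    brute_force_rk(vp$truth$mask)
  }, numeric(1))
  expect_true(all(diff(rks) > 0))
})

test_that("composite scene stacks all channels consistently", {
  sp <- phantom_spec(shape_vox = c(40L, 48L, 48L), voxel_size = c(3, 0.7, 0.7),
                     epidermis = list(mean_thickness_um = 30, sd_um = 3,
                                      surface_roughness_um = 5, z_top = 2L),
                     vessels = list(list(control_points = rbind(c(60, 17, -5),
                                                                c(60, 17, 40)),
                                         radius_um = 5)),
                     droplets = list(n = 3L, radius_range_um = c(5, 8),
                                     layer_z_range_um = c(80, 115)),
                     noise = list(gaussian_sd = 0.05), seed = 69L)
  sc <- avhse_scene(sp)
  expect_named(sc$channels, c("nuclei", "k10", "involucrin", "col4", "bodipy"))
  for (ch in sc$channels) expect_identical(dim(ch$data), c(40L, 48L, 48L))
  expect_equal(volume_fraction(sc$truth$vessels$mask), sc$truth$vessels$vf)
  expect_equal(volume_fraction(sc$truth$adipose$mask), sc$truth$adipose$vf)
})
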