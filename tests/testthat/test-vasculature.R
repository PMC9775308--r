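test_that("vesselness responds to tubes and stays silent elsewhere", {
  # constant volume: zero Hessian, zero response
  expect_true(all(vesselness(grid3(array(3, c(10, 10, 10))), 2)$data == 0))
  # straight tube: centreline response dominates background by >= 10x
  sp <- phantom_spec(shape_vox = c(48L, 48L, 48L), voxel_size = c(1, 1, 1),
                     vessels = list(list(control_points = rbind(c(24, 24, -8),
                                                                c(24, 24, 56)),
                                         radius_um = 4)))
  vp <- make_vessel_phantom(sp, blur_sigma_um = 1)
  v <- vesselness(vp$col4, scales_um = c(2, 4, 6))
  ctr <- mean(v$data[24, 24, 10:38])
  bg <- mean(v$data[8, 8, 10:38]) + 1e-6
  expect_gte(ctr / bg, 10)
  # a solid sphere of equal radius is suppressed relative to the tube
  sph <- array(0, c(48, 48, 48))
  for (z in 1:48) for (y in 1:48) for (x in 1:48)
    if ((z - 24)^2 + (y - 24)^2 + (x - 24)^2 <= 16) sph[z, y, x] <- 1
  vs <- vesselness(grid3(sph), scales_um = c(2, 4, 6))
  expect_lt(vs$data[24, 24, 24], 0.5 * ctr)
  expect_error(vesselness(vp$col4, numeric(0)), "empty")
})

test_that("vessel segmentation keeps tubes and discards speckle", {
  expect_false(any(segment_vessels(grid3(array(0, c(6, 6, 6))))$mask))
  sp <- phantom_spec(shape_vox = c(40L, 40L, 40L), voxel_size = c(1, 1, 1),
                     vessels = list(list(control_points = rbind(c(20, 20, -8),
                                                                c(20, 20, 48)),
                                         radius_um = 4)))
  vp <- make_vessel_phantom(sp, blur_sigma_um = 1)
  v <- vesselness(vp$col4, scales_um = c(3, 4, 6))
  sv <- segment_vessels(v, 0.3, 0.6, 20L)
  lab <- skinquant:::.label_components_cpp(as.logical(sv$mask), dim(sv$mask), 26L)
  expect_equal(max(lab), 1L)  # one connected tube
  # speckle voxels below the size threshold vanish
  spk <- v
  set.seed(51)
  for (i in 1:5) spk$data[sample(40, 1), sample(40, 1), sample(40, 1)] <- max(v$data)
  sv2 <- segment_vessels(spk, 0.3, 0.6, 20L)
  expect_lte(sum(sv2$mask & !sv$mask), 5L) # no new structures beyond the speckles
  lab2 <- skinquant:::.label_components_cpp(as.logical(sv2$mask), dim(sv2$mask), 26L)
  expect_equal(max(lab2), 1L)
})

test_that("skeletonization yields centred, connectivity-preserving curves", {
  # a 1-voxel-wide line is already minimal
  line <- array(FALSE, c(3, 3, 20)); line[2, 2, 3:18] <- TRUE
  pts <- skeletonize(binary_volume(line, c(1, 1, 1)))
  expect_equal(nrow(pts), 16L)
  expect_true(all(pts[, 1] == 2 & pts[, 2] == 2))
  # axis-aligned cylinder r = 4, length 50: within 1 voxel of axis, length >= 45
  cyl <- cylinder_mask(11, 11, 56, 6, 6, 4, 4:53)
  p2 <- skeletonize(binary_volume(cyl, c(1, 1, 1)))
  ax <- sqrt((p2[, 1] - 6)^2 + (p2[, 2] - 6)^2)
  expect_lte(max(ax), 1)
  expect_gte(nrow(p2), 45L)
  expect_true(all(cyl[p2]))            # skeleton lies inside the mask
  expect_equal(skeleton_components(p2), 1L)
  # two disjoint tubes give two disjoint skeleton components
  two <- cylinder_mask(17, 17, 40, 4, 4, 2.5, 3:38) |
    cylinder_mask(17, 17, 40, 13, 13, 2.5, 3:38)
  p3 <- skeletonize(binary_volume(two, c(1, 1, 1)))
  expect_equal(skeleton_components(p3), 2L)
  expect_error(skeletonize(binary_volume(array(FALSE, c(2, 2, 2)), c(1, 1, 1))),
               "empty")
})

test_that("diameters come from the physical-unit distance transform", {
  # digital cylinder r = 5 in isotropic 1 um voxels: median diameter 10 +/- 1
  cyl <- cylinder_mask(13, 13, 40, 7, 7, 5, 3:38)
  bv <- binary_volume(cyl, c(1, 1, 1))
  pts <- skeletonize(bv)
  di <- diameters_along_skeleton(bv, pts)
  expect_lte(abs(di$median_um - 10), 1)
  # centre-to-centre convention: an isolated voxel reads diameter 2
  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  sb <- binary_volume(single, c(1, 1, 1))
  ds <- diameters_along_skeleton(sb, matrix(c(3, 3, 3), 1, 3))
  expect_equal(ds$median_um, 2)
  # doubling the voxel size doubles every diameter (unit linearity)
  di2 <- diameters_along_skeleton(bv, pts, voxel_size = c(2, 2, 2))
  expect_equal(di2$diameters_um, 2 * di$diameters_um)
  expect_error(diameters_along_skeleton(sb, matrix(c(1, 1, 1), 1, 3)), "outside")
})

test_that("diffusion length equals the coverage quantile of tissue distances", {
  # all-vessel mask: nothing to diffuse across
  expect_equal(diffusion_length(binary_volume(array(TRUE, c(3, 3, 3)), c(1, 1, 1))), 0)
  # a vessel plane at z = 1 in a 100-plane isotropic volume: distances per
  # column are exactly 1..99, so R_k is their 90th percentile
  pl <- array(FALSE, c(100, 3, 3)); pl[1, , ] <- TRUE
  bv <- binary_volume(pl, c(1, 1, 1))
  expect_equal(diffusion_length(bv),
               unname(quantile(rep(1:99, 9), 0.9, type = 7)))
  # adding vessel voxels never increases R_k
  set.seed(52)
  m <- array(runif(20^3) < 0.02, c(20, 20, 20)); m[1, 1, 1] <- TRUE
  b1 <- binary_volume(m, c(3, 0.7, 0.7))
  m2 <- m; m2[sample(which(!m), 50)] <- TRUE
  b2 <- binary_volume(m2, c(3, 0.7, 0.7))
  expect_lte(diffusion_length(b2), diffusion_length(b1))
  expect_error(diffusion_length(binary_volume(array(FALSE, c(2, 2, 2)), c(1, 1, 1))),
               "empty")
  expect_error(diffusion_length(b1, coverage = 1.2), "coverage")
})

test_that("vascular metrics average sub-volume readouts per sample", {
  cyl <- cylinder_mask(13, 13, 30, 7, 7, 4, 3:28)
  n1 <- vessel_network(binary_volume(cyl, c(1, 1, 1)))
  expect_true(all(cyl[n1$skeleton_points]))
  r1 <- vascular_metrics(n1)
  # identical sub-volumes reproduce the single-volume metrics
  r2 <- vascular_metrics(list(n1, n1))
  expect_equal(r2$median_diameter_um, r1$median_diameter_um)
  expect_equal(r2$vascular_vf, r1$vascular_vf)
  expect_equal(r2$rk_um, r1$rk_um)
  expect_equal(r2$n_subvolumes, 2L)
  # volume fractions average across tiles
  small <- cylinder_mask(13, 13, 30, 7, 7, 2, 3:28)
  n2 <- vessel_network(binary_volume(small, c(1, 1, 1)))
  r3 <- vascular_metrics(list(n1, n2))
  expect_equal(r3$vascular_vf, mean(c(mean(cyl), mean(small))))
  # phantom network with known true VF recovered exactly through the layer
  expect_equal(r1$vascular_vf, mean(cyl))
})
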