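test_that("auto_crop isolates the interior air region", {
  b <- cached_phantom(3)
  d <- dim(b$volume$data)
  # pad 20 parenchyma slices on each z side
  pad <- array(b$spec$hu_parenchyma, dim = c(d[1] + 40L, d[2], d[3]))
  pad[20L + seq_len(d[1]), , ] <- b$volume$data
  vol <- volume_image(pad, spacing = b$volume$spacing,
                      origin = b$volume$origin - c(20, 0, 0) * b$volume$spacing)
  cr <- auto_crop(vol)
  lum_z <- range(which(apply(b$lumen_mask$data, 1, any)))
  crop_z <- c(cr$offset_voxels[1] + 1L, cr$offset_voxels[1] + dim(cr$volume$data)[1])
  expect_equal(crop_z[1], lum_z[1] + 20L - 2L)
  expect_equal(crop_z[2], lum_z[2] + 20L + 2L)
  # no ground-truth lumen voxel is lost
  lum_idx <- which(b$lumen_mask$data, arr.ind = TRUE)
  lum_idx[, 1] <- lum_idx[, 1] + 20L
  inside <- lum_idx[, 1] > cr$offset_voxels[1] &
    lum_idx[, 1] <= cr$offset_voxels[1] + dim(cr$volume$data)[1] &
    lum_idx[, 2] > cr$offset_voxels[2] &
    lum_idx[, 2] <= cr$offset_voxels[2] + dim(cr$volume$data)[2] &
    lum_idx[, 3] > cr$offset_voxels[3] &
    lum_idx[, 3] <= cr$offset_voxels[3] + dim(cr$volume$data)[3]
  expect_true(all(inside))
})

test_that("auto_crop errors when no interior air exists", {
  flat <- volume_image(array(-850, dim = c(20, 20, 20)))
  expect_error(auto_crop(flat), "no lung-like region")
})

test_that("crop then uncrop restores voxel positions exactly", {
  b <- mini_phantom(2L)
  cr <- auto_crop(b$volume)
  m <- binary_mask(array(FALSE, dim = dim(cr$volume$data)),
                   spacing = cr$volume$spacing, origin = cr$volume$origin)
  cd <- dim(cr$volume$data)
  m$data[ceiling(cd[1] / 2), ceiling(cd[2] / 2), ceiling(cd[3] / 2)] <- TRUE
  full <- uncrop_mask(m, cr, original_origin = b$volume$origin)
  expect_identical(dim(full$data), dim(b$volume$data))
  pos_full <- which(full$data, arr.ind = TRUE)[1, ]
  pos_crop <- which(m$data, arr.ind = TRUE)[1, ]
  expect_equal(unname(pos_full - pos_crop), cr$offset_voxels)
})

test_that("tube probability is zero on constant input and bounded in [0,1]", {
  flat <- volume_image(array(-850, dim = c(30, 30, 30)),
                       spacing = c(0.5, 0.5, 0.5))
  tpm <- tube_probability(flat, radii_mm = c(1.5, 3))
  expect_true(all(tpm$data == 0))
  b <- mini_phantom(2L)
  tpm2 <- tube_probability(b$volume, radii_mm = c(1, 1.5, 2))
  expect_true(all(tpm2$data >= 0 & tpm2$data <= 1))
  expect_equal(max(tpm2$data), 1)
})

test_that("tube probability is invariant to constant HU offsets", {
  b <- mini_phantom(2L)
  t1 <- tube_probability(b$volume, radii_mm = c(1, 1.5, 2))
  shifted <- volume_image(b$volume$data + 300, spacing = b$volume$spacing,
                          origin = b$volume$origin)
  t2 <- tube_probability(shifted, radii_mm = c(1, 1.5, 2))
  expect_equal(t1$data, t2$data, tolerance = 1e-10)
})

test_that("slice-wise response maxima track the axis of a straight tube", {
  tube <- straight_tube_volume(radius_mm = 4)
  tpm <- tube_probability(tube$volume, radii_mm = c(2, 3, 4, 5))
  zz <- seq(tube$z_range[1] + 10L, tube$z_range[2] - 10L, by = 5L)
  for (z in zz) {
    sl <- tpm$data[z, , ]
    am <- which(sl == max(sl), arr.ind = TRUE)[1, ]
    expect_true(all(abs(am - tube$axis_yx) <= 1),
                info = sprintf("slice %d argmax (%d,%d)", z, am[1], am[2]))
  }
})

test_that("mean response inside the lumen exceeds outside on seeded phantoms", {
  for (sd in c(1L, 2L)) {
    b <- mini_phantom(2L, seed = sd, noise_sigma_hu = 20)
    tpm <- tube_probability(b$volume, radii_mm = c(1, 1.5, 2))
    expect_gt(mean(tpm$data[b$lumen_mask$data]),
              mean(tpm$data[!b$lumen_mask$data]))
  }
})

test_that("scales below the voxel spacing are rejected", {
  b <- mini_phantom(2L)
  expect_error(tube_probability(b$volume, radii_mm = c(0.2, 2)), "spacing")
  expect_error(tube_probability(b$volume, radii_mm = numeric(0)), "nonempty")
})
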