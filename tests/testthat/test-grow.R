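trachea_seed <- function(bundle, depth_mm = 5) {
  p <- bundle$tree$points[1, , drop = FALSE]
  p[1] <- p[1] - depth_mm
  airtree:::world_to_voxel(p, bundle$volume$spacing, bundle$volume$origin)[1, ]
}

test_that("a lumen-bracketing threshold interval reproduces the lumen exactly", {
  b <- cached_phantom(3)
  m <- region_grow_threshold(b$volume, trachea_seed(b), -1100, -925)
  expect_identical(m$data, b$lumen_mask$data)
})

test_that("a punched wall hole makes threshold growing leak", {
  bh <- punch_wall_hole(cached_phantom(3))
  m <- region_grow_threshold(bh$volume, trachea_seed(bh), -1100, -500)
  expect_gt(mask_volume(m), mask_volume(bh$lumen_mask))
  # the excess is the flood through the hole into the parenchyma
  expect_gt(leakage_stats(m, bh$labels)$volume_mm3, 0)
})

test_that("seeds outside the interval or the grid are refused", {
  b <- mini_phantom(2L)
  par_vox <- which(b$volume$data == b$spec$hu_parenchyma, arr.ind = TRUE)[1, ]
  expect_error(region_grow_threshold(b$volume, par_vox, -1100, -925),
               "seed not in threshold interval")
  expect_error(region_grow_threshold(b$volume, c(0, 1, 1), -1100, -925),
               "outside")
})

test_that("growing a larger interval never shrinks the region", {
  b <- mini_phantom(2L, noise_sigma_hu = 10)
  s <- trachea_seed(b, depth_mm = 2)
  m1 <- region_grow_threshold(b$volume, s, -1060, -940)
  m2 <- region_grow_threshold(b$volume, s, -1100, -900)
  expect_true(all(m2$data[m1$data]))
})

test_that("connectivity 6 yields a subset of connectivity 26", {
  b <- mini_phantom(2L)
  s <- trachea_seed(b, depth_mm = 2)
  m6 <- region_grow_threshold(b$volume, s, -1100, -925, connectivity = 6L)
  m26 <- region_grow_threshold(b$volume, s, -1100, -925, connectivity = 26L)
  expect_true(all(m26$data[m6$data]))
})

test_that("centerline-seeded growth recovers the lumen with high overlap", {
  b <- cached_phantom(3)
  m <- segment_from_centerline(b$volume, b$tree, dilation_radius_mm = 1)
  inter <- sum(m$data & b$lumen_mask$data)
  dice <- 2 * inter / (sum(m$data) + sum(b$lumen_mask$data))
  expect_gte(dice, 0.95)
  # the mask contains every seed voxel
  seeds <- array(airtree:::.cpp_stamp_balls(dim(b$volume$data),
                                            b$volume$spacing, b$volume$origin,
                                            b$tree$points, 1),
                 dim = dim(b$volume$data))
  expect_true(all(m$data[seeds]))
})

test_that("disabling dilation and gradient growth leaves only point voxels", {
  b <- mini_phantom(2L)
  m <- segment_from_centerline(b$volume, b$tree, dilation_radius_mm = 0,
                               gradient_factor = 0)
  v <- airtree:::world_to_voxel(b$tree$points, b$volume$spacing,
                                b$volume$origin)
  want <- array(FALSE, dim = dim(b$volume$data))
  want[unique((v[, 1] - 1) + dim(want)[1] *
                ((v[, 2] - 1) + dim(want)[2] * (v[, 3] - 1))) + 1] <- TRUE
  expect_identical(m$data, want)
})

test_that("no voxel at or above the HU ceiling is grown outside the seeds", {
  b <- cached_phantom(3)
  m <- segment_from_centerline(b$volume, b$tree, dilation_radius_mm = 1,
                               hu_ceiling = -500)
  seeds <- array(airtree:::.cpp_stamp_balls(dim(b$volume$data),
                                            b$volume$spacing, b$volume$origin,
                                            b$tree$points, 1),
                 dim = dim(b$volume$data))
  grown <- m$data & !seeds
  expect_true(all(b$volume$data[grown] < -500))
})

test_that("gradient gating leaks strictly less than threshold growing", {
  bh <- punch_wall_hole(cached_phantom(3))
  m_thr <- region_grow_threshold(bh$volume, trachea_seed(bh), -1100, -500)
  m_tsf <- segment_from_centerline(bh$volume, bh$tree, dilation_radius_mm = 1)
  l_thr <- leakage_stats(m_thr, bh$labels)
  l_tsf <- leakage_stats(m_tsf, bh$labels)
  expect_lt(l_tsf$volume_mm3, l_thr$volume_mm3)
})

test_that("empty or out-of-volume trees are rejected", {
  b <- mini_phantom(2L)
  far <- centerline_tree(cbind(z = 500, y = 500, x = 500),
                         list(list(point_ids = 1L, generation = 1L,
                                   parent = NA)))
  expect_error(segment_from_centerline(b$volume, far), "inside the volume")
})
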