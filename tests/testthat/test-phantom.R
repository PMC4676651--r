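test_that("phantom geometry follows the dichotomous construction", {
  b1 <- generate_phantom(phantom_spec(1))
  expect_length(b1$tree$branches, 1L)
  expect_equal(branches_per_generation(b1$tree)$max_generation, 1L)

  b4 <- cached_phantom(4)
  h <- branches_per_generation(b4$tree)
  expect_identical(unname(h$counts), c(1L, 2L, 4L, 8L))
  expect_equal(h$total_branches, 15L)

  # generation-3 radius follows the taper
  spec <- phantom_spec(3, root_radius_mm = 9, radius_taper = 0.7)
  expect_equal(spec$radii_mm[3], 9 * 0.7^2)
})

test_that("phantom is deterministic for a fixed seed", {
  s <- mini_spec(2L, seed = 42L, noise_sigma_hu = 15)
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$lumen_mask$data, b$lumen_mask$data)
  c2 <- generate_phantom(mini_spec(2L, seed = 43L, noise_sigma_hu = 15))
  expect_false(identical(a$volume$data, c2$volume$data))
})

test_that("noise-free phantom separates lumen from wall by intensity", {
  b <- mini_phantom(2L)
  hu_par <- b$spec$hu_parenchyma
  expect_true(all(b$volume$data[b$lumen_mask$data] < hu_par))
  wall <- b$volume$data > hu_par
  expect_true(all(b$volume$data[wall] == b$spec$hu_wall))
})

test_that("ground-truth tree lies inside the lumen and is exact", {
  b <- cached_phantom(3)
  d <- dim(b$lumen_mask$data)
  v <- airtree:::world_to_voxel(b$tree$points, b$volume$spacing,
                                b$volume$origin)
  lin <- (v[, 1] - 1) + d[1] * ((v[, 2] - 1) + d[2] * (v[, 3] - 1)) + 1
  expect_true(all(b$lumen_mask$data[lin]))
  validate_centerline_tree(b$tree)
  # branch lengths match their analytic construction to half a voxel
  gens <- vapply(b$tree$branches, function(x) x$generation, 1L)
  lens <- vapply(b$tree$branches, function(x) x$length_mm, 1)
  expect_true(all(abs(lens - b$spec$lengths_mm[gens]) <=
                    max(b$spec$spacing_mm) / 2))
})

test_that("reference labels partition the grid with a one-voxel rind", {
  b <- mini_phantom(2L)
  lab <- b$labels$labels
  expect_true(all(lab %in% c(1L, 2L, 3L)))
  expect_identical(lab == 1L, b$lumen_mask$data)
  # unknown voxels all touch the lumen; no wrong voxel does
  d <- dim(lab)
  rind <- array(airtree:::.cpp_dilate26(b$lumen_mask$data, d), dim = d) &
    !b$lumen_mask$data
  expect_identical(lab == 3L, rind)
  expect_true(all(b$labels$branch_id[b$lumen_mask$data] > 0L))
  # trachea/main-bronchus sub-masks sit inside the lumen
  expect_true(all(b$lumen_mask$data[b$labels$trachea_mask$data]))
  expect_true(all(b$lumen_mask$data[b$labels$main_bronchi_mask$data]))
})

test_that("lumen volume matches the analytic capsule union within 5%", {
  spec <- mini_spec(2L)
  b <- mini_phantom(2L)
  vox <- mask_volume(b$lumen_mask)
  ana <- oracle_capsule_volume(spec)
  expect_lt(abs(vox - ana) / ana, 0.05)
})

test_that("unresolvable tubes are refused with the offending generation", {
  expect_error(phantom_spec(6, root_radius_mm = 9, radius_taper = 0.5,
                            spacing_mm = 0.5),
               "generation [45]")
  expect_error(phantom_spec(2, hu_lumen = -800, hu_parenchyma = -850),
               "hu_lumen")
})

test_that("corrupt_segmentation drops generations and plants separated leaks", {
  b <- cached_phantom(4)
  # identity when nothing is dropped or leaked
  id <- corrupt_segmentation(b, 99L)
  expect_identical(id$data, b$lumen_mask$data)

  kept <- corrupt_segmentation(b, 2L)
  gens <- vapply(b$tree$branches, function(x) x$generation, 1L)
  keep_ids <- which(gens <= 2L)
  expect_identical(kept$data,
                   b$lumen_mask$data &
                     array(b$labels$branch_id %in% keep_ids,
                           dim = dim(b$lumen_mask$data)))

  cs <- corrupt_segmentation(b, 3L, leak_blobs = 3L, leak_voxels_each = 10L,
                             seed = 5L)
  lk <- leakage_stats(cs, b$labels)
  expect_identical(lk$count, 3L)
  expect_equal(lk$volume_mm3, 30 * prod(b$volume$spacing))
  # leak voxels live strictly outside correct and unknown
  extra <- cs$data & !b$lumen_mask$data
  expect_true(all(b$labels$labels[extra] == 2L))
})
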