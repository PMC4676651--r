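test_that("a one-generation phantom yields a single branch of the right length", {
  b <- cached_phantom(1)
  tpm <- tube_probability(b$volume)
  tr <- extract_centerline(tpm, b$volume)
  expect_length(tr$branches, 1L)
  expect_lt(abs(total_length(tr) - b$spec$lengths_mm[1]) / b$spec$lengths_mm[1],
            0.05)
})

test_that("a three-generation phantom is recovered branch for branch", {
  b <- cached_phantom(3)
  cr <- auto_crop(b$volume)
  tpm <- tube_probability(cr$volume)
  tr <- extract_centerline(tpm, cr$volume)
  h <- branches_per_generation(tr)
  expect_identical(unname(h$counts), c(1L, 2L, 4L))
  validate_centerline_tree(tr)
})

test_that("an unreachable probability threshold is reported", {
  b <- mini_phantom(2L)
  tpm <- tube_probability(b$volume, radii_mm = c(1, 1.5, 2))
  tpm$data <- tpm$data * 0.5  # max is now 0.5
  expect_error(extract_centerline(tpm, b$volume, probability_threshold = 0.99),
               "no airway candidate")
})

test_that("thinning a straight cylinder stays within one voxel of its axis", {
  d <- c(70L, 15L, 15L)
  m <- array(FALSE, dim = d)
  yy <- matrix(seq_len(d[2]), d[2], d[3])
  xx <- t(matrix(seq_len(d[3]), d[3], d[2]))
  disc <- (yy - 8)^2 + (xx - 8)^2 <= 3^2
  for (z in 6:65) m[z, , ] <- disc
  tr <- thinning_centerline(binary_mask(m, spacing = c(1, 1, 1)))
  expect_length(tr$branches, 1L)
  v <- airtree:::world_to_voxel(tr$points, c(1, 1, 1), c(0, 0, 0))
  expect_true(all(abs(v[, 2] - 8) <= 1))
  expect_true(all(abs(v[, 3] - 8) <= 1))
})

test_that("thinning the ground-truth lumen recovers the full binary tree", {
  b <- cached_phantom(4)
  tr <- thinning_centerline(b$lumen_mask)
  h <- branches_per_generation(tr)
  expect_identical(unname(h$counts), c(1L, 2L, 4L, 8L))
  expect_equal(h$max_generation, 4L)
})

test_that("probability and thinning routes agree on the phantom histogram", {
  b <- cached_phantom(3)
  cr <- auto_crop(b$volume)
  tr_tdf <- extract_centerline(tube_probability(cr$volume), cr$volume)
  tr_thin <- thinning_centerline(b$lumen_mask)
  h1 <- branches_per_generation(tr_tdf)$counts
  h2 <- branches_per_generation(tr_thin)$counts
  expect_equal(length(h1), length(h2))
  expect_true(all(abs(h1 - h2) <= 1))
})

test_that("a single voxel thins to a one-point, zero-length tree", {
  m <- array(FALSE, dim = c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  tr <- thinning_centerline(binary_mask(m, spacing = c(1, 1, 1)))
  expect_equal(nrow(tr$points), 1L)
  expect_length(tr$branches, 1L)
  expect_equal(total_length(tr), 0)
  expect_error(thinning_centerline(
    binary_mask(array(FALSE, dim = c(3, 3, 3)))), "empty")
})

test_that("total tree length is invariant under grid translation", {
  b <- mini_phantom(2L)
  t1 <- thinning_centerline(b$lumen_mask)
  shifted <- binary_mask(b$lumen_mask$data, spacing = b$lumen_mask$spacing,
                         origin = b$lumen_mask$origin + c(7, -3, 11))
  t2 <- thinning_centerline(shifted)
  expect_equal(total_length(t1), total_length(t2), tolerance = 1e-9)
})

test_that("prune_spurs is an identity at zero length and idempotent", {
  b <- mini_phantom(2L)
  tr <- b$tree
  expect_identical(prune_spurs(tr, 0), tr)
  p1 <- prune_spurs(tr, 3)
  p2 <- prune_spurs(p1, 3)
  expect_equal(length(p1$branches), length(p2$branches))
  expect_equal(total_length(p1), total_length(p2))
})

test_that("pruning a sub-length twig dissolves its junction", {
  pts <- rbind(c(10, 0, 0), c(5, 0, 0), c(0, 0, 0), c(4.7, 0.3, 0))
  tr <- centerline_tree(pts, list(
    list(point_ids = 1:2, generation = 1L, parent = NA),
    list(point_ids = 2:3, generation = 2L, parent = 1L),
    list(point_ids = c(2L, 4L), generation = 2L, parent = 1L)))
  pr <- prune_spurs(tr, 1)
  expect_length(pr$branches, 1L)
  expect_equal(total_length(pr), 10)
})
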