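test_that("generation histograms count branches by depth", {
  one <- centerline_tree(cbind(z = c(1, 0), y = 0, x = 0),
                         list(list(point_ids = 1:2, generation = 1L,
                                   parent = NA)))
  h <- branches_per_generation(one)
  expect_identical(unname(h$counts), 1L)
  expect_equal(h$total_branches, 1L)
  expect_equal(h$max_generation, 1L)

  b5 <- cached_phantom(5)
  h5 <- branches_per_generation(b5$tree)
  expect_identical(unname(h5$counts), c(1L, 2L, 4L, 8L, 16L))
  expect_equal(h5$total_branches, 31L)
})

test_that("total length sums branch polylines without double counting", {
  pts <- cbind(z = seq(10, 0, by = -1), y = 0, x = 0)
  tr <- centerline_tree(pts, list(list(point_ids = 1:11, generation = 1L,
                                       parent = NA)))
  expect_equal(total_length(tr), 10)

  # Y of three 5 mm branches
  p <- rbind(c(5, 0, 0), c(0, 0, 0), c(-4, 3, 0), c(-4, -3, 0))
  y <- centerline_tree(p, list(
    list(point_ids = 1:2, generation = 1L, parent = NA),
    list(point_ids = c(2L, 3L), generation = 2L, parent = 1L),
    list(point_ids = c(2L, 4L), generation = 2L, parent = 1L)))
  expect_equal(total_length(y), 15)
})

test_that("total length is invariant under rigid rotation", {
  b <- mini_phantom(2L)
  tr <- b$tree
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- tr
  rot$points <- tr$points %*% R
  rot <- centerline_tree(rot$points, tr$branches, tr$root_point,
                         validate = FALSE)
  expect_lt(abs(total_length(rot) - total_length(tr)), 1e-6)
})

test_that("mask volume is voxel count times voxel volume, and additive", {
  m <- array(FALSE, dim = c(20, 10, 10))
  m[seq_len(1000)] <- TRUE
  bm <- binary_mask(m, spacing = c(0.5, 0.5, 0.5))
  expect_equal(mask_volume(bm), 125)
  empty <- binary_mask(array(FALSE, dim = c(4, 4, 4)),
                       spacing = c(0.5, 0.5, 0.5))
  expect_equal(mask_volume(empty), 0)
  # additivity over a disjoint split
  a <- bm; a$data[, , 6:10] <- FALSE
  b <- bm; b$data[, , 1:5] <- FALSE
  expect_equal(mask_volume(a) + mask_volume(b), mask_volume(bm))
})

test_that("pearson matches the product-moment definition", {
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson(c(1, 2, 3), -c(1, 2, 3)), -1)
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  byhand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(byhand, 0.8)
  expect_equal(pearson(x, y), byhand)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson(1:3, 1:4), "equal length")
})

test_that("metric tables carry per-generation rows and totals", {
  b <- cached_phantom(3)
  df <- tree_metrics_table(b$tree, b$lumen_mask)
  expect_equal(nrow(df), 3L)
  expect_equal(df$branches, c(1L, 2L, 4L))
  expect_equal(sum(df$length_mm), attr(df, "total_length_mm"))
  expect_equal(attr(df, "volume_mm3"), mask_volume(b$lumen_mask))
})
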