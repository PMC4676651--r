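test_that("evaluating the ground truth against itself is perfect", {
  b <- cached_phantom(3)
  ev <- evaluate_segmentation(b$lumen_mask, b$tree, b$labels, b$tree)
  expect_equal(ev$branch_detected_pct, 100)
  expect_equal(ev$tree_length_detected_pct, 100)
  expect_equal(ev$false_positive_rate_pct, 0)
  expect_identical(ev$leakage_count, 0L)
  expect_equal(ev$leakage_volume_mm3, 0)
  expect_equal(ev$branch_count, ev$branch_total)
})

test_that("overlap counts honour the unknown and airway exclusions", {
  b <- mini_phantom(2L)
  oc <- overlap_counts(b$lumen_mask, b$labels)
  excl <- b$labels$trachea_mask$data | b$labels$main_bronchi_mask$data
  expect_equal(oc[["Nc"]], sum(b$lumen_mask$data & !excl))
  expect_equal(oc[["Nw"]], 0L)

  # a segmentation entirely inside the unknown rind counts nowhere
  rind <- binary_mask(b$labels$labels == 3L, b$volume$spacing,
                      b$volume$origin)
  oc2 <- overlap_counts(rind, b$labels)
  expect_equal(unname(oc2), c(0L, 0L))
  bad <- binary_mask(array(TRUE, dim = c(2, 2, 2)))
  expect_error(overlap_counts(bad, b$labels), "dimensions")
})

test_that("false positive rate follows Nw / (Nc + Nw)", {
  expect_equal(false_positive_rate(99, 1), 1)
  expect_equal(false_positive_rate(50, 0), 0)
  expect_equal(false_positive_rate(930, 70), 7)
  expect_error(false_positive_rate(0, 0), "empty segmentation")
})

test_that("branch detection counts reference branches hit by the candidate", {
  b <- cached_phantom(4)
  bd <- branch_detection(b$tree, b$labels, b$tree)
  expect_equal(bd$Nref, 14L)  # 15 branches minus the trachea
  expect_equal(bd$Nseg, 14L)
  expect_equal(bd$pct, 100)

  seg_tree <- truncate_tree(b$tree, 3L)
  bd3 <- branch_detection(seg_tree, b$labels, b$tree)
  expect_equal(bd3$Nseg, 6L)
  expect_equal(bd3$pct, 6 / 14 * 100, tolerance = 1e-12)

  bd0 <- branch_detection(NULL, b$labels, b$tree)
  expect_equal(bd0$Nseg, 0L)
  expect_equal(bd0$pct, 0)
})

test_that("tree length detected measures covered reference arclength", {
  b <- cached_phantom(3)
  tl <- tree_length_detected(b$lumen_mask, b$tree, b$labels)
  expect_equal(tl$pct, 100)
  expect_equal(tl$Lseg_cm, tl$Lref_cm)

  # cover exactly the first half (by arclength) of every non-trachea branch
  d <- dim(b$lumen_mask$data)
  half <- array(FALSE, dim = d)
  gens <- vapply(b$tree$branches, function(x) x$generation, 1L)
  step <- max(b$volume$spacing) / 2
  for (br in b$tree$branches[gens > 1L]) {
    ids <- br$point_ids
    keep <- ids[seq_len(ceiling(length(ids) / 2))]
    v <- airtree:::world_to_voxel(b$tree$points[keep, , drop = FALSE],
                                  b$volume$spacing, b$volume$origin)
    half[(v[, 1] - 1) + d[1] * ((v[, 2] - 1) + d[2] * (v[, 3] - 1)) + 1] <- TRUE
  }
  tl2 <- tree_length_detected(binary_mask(half, b$volume$spacing,
                                          b$volume$origin),
                              b$tree, b$labels)
  # within one inter-point spacing per branch of the 50% mark
  slack <- length(b$tree$branches[gens > 1L]) * step / (10 * tl2$Lref_cm) * 100
  expect_lt(abs(tl2$pct - 50), slack + 1)

  none <- binary_mask(array(FALSE, dim = d), b$volume$spacing, b$volume$origin)
  expect_equal(tree_length_detected(none, b$tree, b$labels)$pct, 0)
})

test_that("leakage groups wrong voxels by 26-connectivity", {
  b <- mini_phantom(2L)
  d <- dim(b$labels$labels)
  clean <- leakage_stats(b$lumen_mask, b$labels)
  expect_identical(clean$count, 0L)
  expect_equal(clean$volume_mm3, 0)

  # two blobs sharing only a voxel corner are one component
  wrong_at <- which(b$labels$labels == 2L, arr.ind = TRUE)
  m <- array(FALSE, dim = d)
  m[2, 2, 2] <- TRUE; m[3, 3, 3] <- TRUE   # corner-adjacent background corner
  stopifnot(b$labels$labels[2, 2, 2] == 2L, b$labels$labels[3, 3, 3] == 2L)
  lk <- leakage_stats(binary_mask(m, b$volume$spacing, b$volume$origin),
                      b$labels)
  expect_identical(lk$count, 1L)
  expect_equal(lk$volume_mm3, 2 * prod(b$volume$spacing))
})

test_that("flipping trachea voxels changes no reported metric", {
  b <- cached_phantom(3)
  seg_tree <- b$tree
  seg <- corrupt_segmentation(b, 99L, leak_blobs = 1L, leak_voxels_each = 8L,
                              seed = 2L)
  ev1 <- evaluate_segmentation(seg, seg_tree, b$labels, b$tree)
  seg2 <- seg
  seg2$data[b$labels$trachea_mask$data] <- !seg2$data[b$labels$trachea_mask$data]
  ev2 <- evaluate_segmentation(seg2, seg_tree, b$labels, b$tree)
  for (f in c("branch_detected_pct", "tree_length_detected_pct",
              "false_positive_rate_pct", "leakage_count", "Nc", "Nw"))
    expect_equal(ev1[[f]], ev2[[f]], info = f)
})

test_that("adding correct voxels improves or preserves every measure", {
  b <- cached_phantom(3)
  seg_small <- corrupt_segmentation(b, 2L, leak_blobs = 1L,
                                    leak_voxels_each = 8L, seed = 3L)
  seg_big <- seg_small
  seg_big$data[b$lumen_mask$data] <- TRUE
  tree_small <- truncate_tree(b$tree, 2L)
  ev_s <- evaluate_segmentation(seg_small, tree_small, b$labels, b$tree)
  ev_b <- evaluate_segmentation(seg_big, b$tree, b$labels, b$tree)
  expect_gte(ev_b$branch_detected_pct, ev_s$branch_detected_pct)
  expect_gte(ev_b$tree_length_detected_pct, ev_s$tree_length_detected_pct)
  expect_lte(ev_b$false_positive_rate_pct, ev_s$false_positive_rate_pct)
})

test_that("evaluation equals a brute-force recomputation on small phantoms", {
  for (sd in c(1L, 2L)) {
    b <- mini_phantom(2L, seed = sd)
    seg <- corrupt_segmentation(b, 1L, leak_blobs = 2L, leak_voxels_each = 6L,
                                seed = sd + 10L)
    seg_tree <- truncate_tree(b$tree, 1L)
    oc <- overlap_counts(seg, b$labels)
    expect_identical(oc, oracle_overlap_counts(seg, b$labels))
    bd <- branch_detection(seg_tree, b$labels, b$tree)
    ob <- oracle_branch_detection(seg_tree, b$labels, b$tree)
    expect_equal(bd$Nseg, ob$Nseg)
    expect_equal(bd$pct, ob$pct)
    tl <- tree_length_detected(seg, b$tree, b$labels)
    ot <- oracle_tree_length_detected(seg, b$tree, b$labels)
    expect_equal(tl$pct, ot$pct)
    lk <- leakage_stats(seg, b$labels)
    ol <- oracle_leakage_stats(seg, b$labels)
    expect_identical(lk$count, ol$count)
    expect_equal(lk$volume_mm3, ol$volume_mm3)
  }
})

test_that("an empty segmentation is refused by the composite evaluation", {
  b <- mini_phantom(2L)
  empty <- binary_mask(array(FALSE, dim = dim(b$labels$labels)),
                       b$volume$spacing, b$volume$origin)
  expect_error(evaluate_segmentation(empty, NULL, b$labels, b$tree),
               "empty segmentation")
})
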