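# EXACT09-style reference evaluation: a candidate segmentation is scored
# against voxel labels correct / wrong / unknown. Unknown voxels never count;
# the trachea is excluded from all measures, and the main bronchi are
# additionally excluded from the false-positive-rate counts.

#' Reference labels for segmentation evaluation
#'
#' @param labels 3D integer array over categories 0 = background, 1 =
#'   correct, 2 = wrong, 3 = unknown (mutually exclusive and exhaustive).
#' @param branch_id 3D integer array assigning each correct voxel the index
#'   of its ground-truth branch (0 elsewhere).
#' @param trachea_mask,main_bronchi_mask [binary_mask()] sub-masks of the
#'   correct region (generation 1 and generation 2 voxels).
#' @param spacing,origin Grid geometry (mm).
#' @return An object of class `reference_labels`.
#' @export
reference_labels <- function(labels, branch_id, trachea_mask,
                             main_bronchi_mask, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  if (!all(labels %in% 0:3)) stop("labels must be coded 0..3")
  if (!identical(dim(labels), dim(branch_id)))
    stop("labels and branch_id must share dimensions")
  if (any(labels == LBL_CORRECT & branch_id == 0L))
    stop("every correct voxel needs a branch id")
  structure(list(labels = labels, branch_id = branch_id,
                 trachea_mask = trachea_mask,
                 main_bronchi_mask = main_bronchi_mask,
                 spacing = as.numeric(spacing), origin = as.numeric(origin)),
            class = "reference_labels")
}

#' @export
print.reference_labels <- function(x, ...) {
  cat(sprintf("<reference_labels> %s voxels: %d correct, %d wrong, %d unknown\n",
              paste(dim(x$labels), collapse = "x"),
              sum(x$labels == LBL_CORRECT), sum(x$labels == LBL_WRONG),
              sum(x$labels == LBL_UNKNOWN)))
  invisible(x)
}

#' Correct / wrong overlap counts
#'
#' Counts segmented voxels overlapping the `correct` (Nc) and `wrong` (Nw)
#' reference regions. Voxels overlapping `unknown` count in neither; voxels
#' inside the trachea are excluded from all counting, and voxels inside the
#' main bronchi are excluded from Nc/Nw (the false-positive-rate exclusions).
#'
#' @param seg A [binary_mask()] on the reference grid.
#' @param ref A [reference_labels()].
#' @return Named integer vector `c(Nc = ..., Nw = ...)`.
#' @export
overlap_counts <- function(seg, ref) {
  stopifnot(inherits(seg, "binary_mask"), inherits(ref, "reference_labels"))
  if (!identical(dim(seg$data), dim(ref$labels)))
    stop("segmentation and reference grids differ in dimensions")
  excl <- ref$trachea_mask$data | ref$main_bronchi_mask$data
  s <- seg$data & !excl
  c(Nc = sum(s & ref$labels == LBL_CORRECT),
    Nw = sum(s & ref$labels == LBL_WRONG))
}

#' False-positive rate
#'
#' The fraction of segmented voxels not marked `correct` in the reference:
#' `Nw / (Nc + Nw) * 100`.
#'
#' @param Nc,Nw Overlap counts from [overlap_counts()].
#' @return Percentage in `[0, 100]`.
#' @export
false_positive_rate <- function(Nc, Nw) {
  if (Nc + Nw <= 0) stop("empty segmentation after exclusions")
  Nw / (Nc + Nw) * 100
}

#' Branch detection against the reference tree
#'
#' A reference branch counts as detected iff at least one candidate
#' centerline point falls in a voxel carrying that branch's id. The trachea
#' branch is excluded from both Nseg and Nref.
#'
#' @param seg_tree Candidate [centerline_tree()], or `NULL` for an empty
#'   result.
#' @param ref A [reference_labels()] with populated `branch_id`.
#' @param ref_tree The ground-truth [centerline_tree()].
#' @return List with `Nseg`, `Nref`, `pct`.
#' @export
branch_detection <- function(seg_tree, ref, ref_tree) {
  stopifnot(inherits(ref, "reference_labels"),
            inherits(ref_tree, "centerline_tree"))
  trachea_ids <- which(vapply(ref_tree$branches,
                              function(b) b$generation == 1L, TRUE))
  all_ids <- seq_along(ref_tree$branches)
  eval_ids <- setdiff(all_ids, trachea_ids)
  Nref <- length(eval_ids)
  detected <- integer(0)
  if (!is.null(seg_tree) && nrow(seg_tree$points) > 0L) {
    d <- dim(ref$labels)
    idx <- world_to_voxel(seg_tree$points, ref$spacing, ref$origin)
    ok <- idx[, 1L] >= 1 & idx[, 1L] <= d[1L] &
      idx[, 2L] >= 1 & idx[, 2L] <= d[2L] &
      idx[, 3L] >= 1 & idx[, 3L] <= d[3L]
    idx <- idx[ok, , drop = FALSE]
    lin <- (idx[, 1L] - 1L) + d[1L] * ((idx[, 2L] - 1L) + d[2L] * (idx[, 3L] - 1L)) + 1L
    hit <- ref$branch_id[lin]
    detected <- intersect(unique(hit[hit > 0L]), eval_ids)
  }
  Nseg <- length(detected)
  list(Nseg = Nseg, Nref = Nref,
       pct = if (Nref > 0) Nseg / Nref * 100 else 0,
       detected_ids = sort(detected))
}

#' Tree length detected by a segmentation
#'
#' The reference-centerline length covered by the segmentation: a segment
#' between consecutive reference points counts iff both endpoints lie in
#' segmented voxels. The trachea branch is excluded; lengths are reported in
#' cm.
#'
#' @param seg A [binary_mask()] on the reference grid.
#' @param ref_tree The ground-truth [centerline_tree()].
#' @param ref A [reference_labels()] (grid geometry).
#' @return List with `Lseg_cm`, `Lref_cm`, `pct`.
#' @export
tree_length_detected <- function(seg, ref_tree, ref) {
  stopifnot(inherits(seg, "binary_mask"), inherits(ref_tree, "centerline_tree"))
  d <- dim(seg$data)
  idx <- world_to_voxel(ref_tree$points, ref$spacing, ref$origin)
  inside <- idx[, 1L] >= 1 & idx[, 1L] <= d[1L] &
    idx[, 2L] >= 1 & idx[, 2L] <= d[2L] &
    idx[, 3L] >= 1 & idx[, 3L] <= d[3L]
  lin <- rep(NA_integer_, nrow(idx))
  lin[inside] <- (idx[inside, 1L] - 1L) +
    d[1L] * ((idx[inside, 2L] - 1L) + d[2L] * (idx[inside, 3L] - 1L)) + 1L
  covered <- rep(FALSE, nrow(idx))
  covered[inside] <- seg$data[lin[inside]]
  Lref <- 0
  Lseg <- 0
  for (b in ref_tree$branches) {
    if (b$generation == 1L) next  # trachea excluded
    ids <- b$point_ids
    if (length(ids) < 2L) next
    p <- ref_tree$points[ids, , drop = FALSE]
    seglen <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    Lref <- Lref + sum(seglen)
    both <- covered[ids[-length(ids)]] & covered[ids[-1L]]
    Lseg <- Lseg + sum(seglen[both])
  }
  if (Lref <= 0) stop("reference tree has zero length outside the trachea")
  list(Lseg_cm = Lseg / 10, Lref_cm = Lref / 10, pct = Lseg / Lref * 100)
}

#' Leakage count and volume
#'
#' Segmented voxels labelled `wrong` are grouped into 26-connected
#' components: `count` is the number of components and `volume` their total
#' volume in mm^3. Unknown voxels are not leakage.
#'
#' @param seg A [binary_mask()] on the reference grid.
#' @param ref A [reference_labels()].
#' @return List with `count` and `volume_mm3`.
#' @export
leakage_stats <- function(seg, ref) {
  stopifnot(inherits(seg, "binary_mask"), inherits(ref, "reference_labels"))
  if (!identical(dim(seg$data), dim(ref$labels)))
    stop("segmentation and reference grids differ in dimensions")
  d <- dim(seg$data)
  wrongseg <- seg$data & ref$labels == LBL_WRONG
  if (!any(wrongseg)) return(list(count = 0L, volume_mm3 = 0))
  lab <- .cpp_label_components(wrongseg, d, 26L)
  list(count = max(lab), volume_mm3 = sum(wrongseg) * prod(ref$spacing))
}

#' Full reference evaluation of a segmentation
#'
#' Composes [branch_detection()], [tree_length_detected()],
#' [false_positive_rate()] and [leakage_stats()] into one record with the
#' usual reporting fields: branch count and percentage detected, tree length
#' (cm) and percentage detected, leakage count and volume, false-positive
#' rate.
#'
#' @param seg Candidate [binary_mask()].
#' @param seg_tree Candidate [centerline_tree()] (or `NULL`).
#' @param ref A [reference_labels()].
#' @param ref_tree Ground-truth [centerline_tree()].
#' @return An object of class `evaluation_result`.
#' @export
evaluate_segmentation <- function(seg, seg_tree, ref, ref_tree) {
  oc <- overlap_counts(seg, ref)
  fpr <- false_positive_rate(oc[["Nc"]], oc[["Nw"]])
  bd <- branch_detection(seg_tree, ref, ref_tree)
  tl <- tree_length_detected(seg, ref_tree, ref)
  lk <- leakage_stats(seg, ref)
  structure(list(
    branch_count = bd$Nseg, branch_total = bd$Nref,
    branch_detected_pct = bd$pct,
    tree_length_cm = tl$Lseg_cm, tree_length_total_cm = tl$Lref_cm,
    tree_length_detected_pct = tl$pct,
    leakage_count = lk$count, leakage_volume_mm3 = lk$volume_mm3,
    false_positive_rate_pct = fpr,
    Nc = oc[["Nc"]], Nw = oc[["Nw"]]),
    class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("reference evaluation\n")
  cat(sprintf("  branch count        %d / %d (%.1f%% detected)\n",
              x$branch_count, x$branch_total, x$branch_detected_pct))
  cat(sprintf("  tree length         %.2f / %.2f cm (%.1f%% detected)\n",
              x$tree_length_cm, x$tree_length_total_cm,
              x$tree_length_detected_pct))
  cat(sprintf("  leakage             %d component(s), %.2f mm3\n",
              x$leakage_count, x$leakage_volume_mm3))
  cat(sprintf("  false positive rate %.2f%%  (Nc = %d, Nw = %d)\n",
              x$false_positive_rate_pct, x$Nc, x$Nw))
  invisible(x)
}
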