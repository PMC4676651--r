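# Segmentation stage: threshold-interval region growing (the classic
# dynamic-region-growing comparator) and centerline-seeded growing with a
# gradient-calibrated gate against leakage.

#' Threshold-interval seeded region growing
#'
#' Flood-fills from a seed voxel, accepting connected voxels whose intensity
#' lies in `[lower_hu, upper_hu]`. This is the dynamic region growing used as
#' a comparator: prone to leakage through thin or broken airway walls.
#'
#' @param volume A [volume_image()].
#' @param seed_voxel 1-based `(z, y, x)` voxel index of the seed.
#' @param lower_hu,upper_hu Accepted intensity interval (defaults follow the
#'   usual airway settings: -990 to -120 HU).
#' @param connectivity 6 or 26.
#' @return A [binary_mask()].
#' @export
region_grow_threshold <- function(volume, seed_voxel, lower_hu = -990,
                                  upper_hu = -120, connectivity = 26L) {
  stopifnot(inherits(volume, "volume_image"))
  d <- dim(volume$data)
  seed_voxel <- as.integer(seed_voxel)
  if (length(seed_voxel) != 3L || any(seed_voxel < 1L) || any(seed_voxel > d))
    stop("seed voxel outside the volume")
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  hu <- volume$data[seed_voxel[1L], seed_voxel[2L], seed_voxel[3L]]
  if (hu < lower_hu || hu > upper_hu)
    stop(sprintf("seed not in threshold interval: %g HU outside [%g, %g]",
                 hu, lower_hu, upper_hu))
  m <- .cpp_region_grow_range(volume$data, d, seed_voxel - 1L, lower_hu,
                              upper_hu, as.integer(connectivity))
  binary_mask(array(m, dim = d), spacing = volume$spacing,
              origin = volume$origin)
}

#' Segmentation by centerline-seeded, gradient-gated region growing
#'
#' Seeds are all voxels within `dilation_radius_mm` of any centerline point.
#' Growth (26-connected, deterministic FIFO order) accepts a voxel iff its
#' intensity is below `hu_ceiling` and its steepest local intensity gradient
#' (one-sided differences over the 26-neighbourhood, mm-scaled) stays below
#' `gradient_factor` times the wall gradient. The wall gradient is
#' self-calibrated per volume as the 95th percentile of the gradient measure
#' over eligible voxels (below the ceiling) adjacent to ineligible ones — the
#' air-tissue interface. A final one-voxel conditional dilation, restricted
#' to eligible voxels, restores the wall-adjacent lumen rind that the gate
#' necessarily rejects.
#'
#' @param volume A [volume_image()].
#' @param tree A [centerline_tree()] whose points lie inside the volume.
#' @param dilation_radius_mm Seed dilation radius (mm).
#' @param hu_ceiling Upper intensity bound for any segmented voxel.
#' @param gradient_factor Gate multiplier on the calibrated wall gradient.
#'   `0` disables growth: the result is exactly the seed set.
#' @return A [binary_mask()].
#' @export
segment_from_centerline <- function(volume, tree, dilation_radius_mm = 1,
                                    hu_ceiling = -500, gradient_factor = 0.5) {
  stopifnot(inherits(volume, "volume_image"))
  if (!inherits(tree, "centerline_tree") || nrow(tree$points) < 1L)
    stop("centerline tree is empty")
  if (dilation_radius_mm < 0) stop("`dilation_radius_mm` must be >= 0")
  d <- dim(volume$data)
  idx <- world_to_voxel(tree$points, volume$spacing, volume$origin)
  inside <- idx[, 1L] >= 1 & idx[, 1L] <= d[1L] &
    idx[, 2L] >= 1 & idx[, 2L] <= d[2L] &
    idx[, 3L] >= 1 & idx[, 3L] <= d[3L]
  if (!any(inside)) stop("no centerline point lies inside the volume")
  seeds <- .cpp_stamp_balls(d, volume$spacing, volume$origin,
                            tree$points[inside, , drop = FALSE],
                            dilation_radius_mm)
  grad <- array(.cpp_local_gradient3(volume$data, d, volume$spacing), dim = d)
  eligible <- volume$data < hu_ceiling
  interface <- eligible &
    array(.cpp_dilate26(!eligible, d), dim = d)
  g_wall <- if (any(interface)) {
    as.numeric(quantile(grad[interface], 0.95, names = FALSE))
  } else {
    Inf  # nothing to leak into: gate open
  }
  thr <- gradient_factor * g_wall
  if (gradient_factor == 0) thr <- 0
  m <- .cpp_grow_gradient_gate(volume$data, grad, d, seeds, hu_ceiling, thr)
  binary_mask(array(m, dim = d), spacing = volume$spacing,
              origin = volume$origin)
}
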