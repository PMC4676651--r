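# Per-method airway-tree measurements: branch counts per generation, total
# centerline length, segmented volume, and the Pearson correlation used to
# compare measurement series between methods.

#' Branch counts per generation
#'
#' @param tree A [centerline_tree()].
#' @return An object of class `generation_histogram`: list with `counts`
#'   (named integer vector, names are generations), `total_branches` and
#'   `max_generation`.
#' @export
branches_per_generation <- function(tree) {
  stopifnot(inherits(tree, "centerline_tree"))
  gens <- vapply(tree$branches, function(b) b$generation, 1L)
  maxg <- max(gens)
  counts <- tabulate(gens, nbins = maxg)
  names(counts) <- seq_len(maxg)
  structure(list(counts = counts, total_branches = sum(counts),
                 max_generation = maxg),
            class = "generation_histogram")
}

#' @export
print.generation_histogram <- function(x, ...) {
  cat("generation: ", paste(sprintf("%s:%d", names(x$counts), x$counts),
                            collapse = "  "), "\n", sep = "")
  cat(sprintf("total %d branches, max generation %d\n",
              x$total_branches, x$max_generation))
  invisible(x)
}

#' Total centerline length
#'
#' Sum over branches of the Euclidean polyline length in mm. Junction points
#' shared between a parent and its children bound segments on both sides but
#' no segment is counted twice.
#'
#' @param tree A [centerline_tree()].
#' @return Length in mm.
#' @export
total_length <- function(tree) {
  stopifnot(inherits(tree, "centerline_tree"))
  sum(vapply(tree$branches, function(b) b$length_mm, 1))
}

#' Segmented volume
#'
#' Number of foreground voxels multiplied by the volume of a single voxel.
#'
#' @param mask A [binary_mask()].
#' @return Volume in mm^3.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$data) * voxel_volume_mm3(mask)
}

#' Pearson correlation between measurement series
#'
#' Standard product-moment correlation between paired per-case measurement
#' series (e.g. segmented volumes from two methods).
#'
#' @param x,y Numeric vectors of equal length (>= 2), each with nonzero
#'   variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 2L)
    stop("`x` and `y` must have equal length >= 2")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in a measurement series")
  stats::cor(x, y)
}

#' Tabulate tree and mask metrics
#'
#' One row per generation (branch count, summed branch length) plus totals,
#' the shape used to report per-method airway measurements.
#'
#' @param tree A [centerline_tree()].
#' @param mask Optional [binary_mask()] for the segmented volume.
#' @return A data.frame with attributes `total_length_mm`, `volume_mm3`.
#' @export
tree_metrics_table <- function(tree, mask = NULL) {
  h <- branches_per_generation(tree)
  gens <- vapply(tree$branches, function(b) b$generation, 1L)
  lens <- vapply(tree$branches, function(b) b$length_mm, 1)
  df <- data.frame(
    generation = as.integer(names(h$counts)),
    branches = as.integer(h$counts),
    length_mm = vapply(seq_along(h$counts),
                       function(g) sum(lens[gens == g]), 1)
  )
  attr(df, "total_length_mm") <- total_length(tree)
  attr(df, "volume_mm3") <- if (is.null(mask)) NA_real_ else mask_volume(mask)
  df
}
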