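# Core containers. Axis order is (z, y, x), slices first; voxel indices are
# 1-based in R, and world coordinate = origin + (index - 1) * spacing (mm).

#' Create a 3D scalar volume
#'
#' A `volume_image` holds a 3D grid of scalar values (Hounsfield units for CT)
#' together with per-axis voxel spacing and the world position of the first
#' voxel. The internal axis order is `(z, y, x)`: the first array index runs
#' over slices.
#'
#' @param data 3D numeric array, dimensions `(nz, ny, nx)`.
#' @param spacing Numeric length-3, voxel size in mm, `(z, y, x)` order. All
#'   components must be strictly positive.
#' @param origin Numeric length-3, world position (mm) of voxel `(1, 1, 1)`.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers")
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  if (any(!is.finite(data))) stop("voxel values must be finite")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume_image")
}

#' Create a binary mask aligned to a volume
#'
#' @param data 3D logical array.
#' @param spacing,origin Grid geometry, usually inherited from the source
#'   [volume_image()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  storage.mode(data) <- "logical"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "binary_mask")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_image> %d x %d x %d voxels (z,y,x), spacing %s mm, HU range [%g, %g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask> %d x %d x %d voxels (z,y,x), %d foreground\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-8))
}

# world (mm, z/y/x) -> 1-based voxel index, nearest voxel
world_to_voxel <- function(points, spacing, origin) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  idx <- sweep(points, 2, origin, "-")
  idx <- sweep(idx, 2, spacing, "/")
  round(idx) + 1
}

voxel_to_world <- function(idx, spacing, origin) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3)
  sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
}

#' Voxel volume in cubic millimetres
#' @param x A `volume_image` or `binary_mask`.
#' @return Volume of one voxel in mm^3.
#' @export
voxel_volume_mm3 <- function(x) prod(x$spacing)
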