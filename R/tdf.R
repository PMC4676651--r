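# Stage 1-2 of the pipeline: automatic cropping to the lung region and the
# per-voxel tube-probability map (multi-scale Hessian tube-likeness, oriented
# for tubes darker than their surroundings).

#' Automatically crop a CT volume to the lung region
#'
#' Thresholds voxels below `air_threshold_hu`, discards air components that
#' touch the lateral (x/y) image border — body-exterior air — and crops to
#' the bounding box of the remaining air regions (lungs and airways), padded
#' by two voxels and clipped to the image.
#'
#' @param volume A [volume_image()].
#' @param air_threshold_hu Voxels strictly below this are air (default -500).
#' @return An object of class `crop_result`: list with `volume` (the cropped
#'   [volume_image()]), `offset_voxels` (0-based `(z, y, x)` offset of the
#'   crop inside the original grid) and `original_dim`.
#' @export
auto_crop <- function(volume, air_threshold_hu = -500) {
  stopifnot(inherits(volume, "volume_image"))
  d <- dim(volume$data)
  air <- volume$data < air_threshold_hu
  lab <- array(.cpp_label_components(air, d, 6L), dim = d)
  border_labels <- unique(c(lab[, 1L, ], lab[, d[2L], ],
                            lab[, , 1L], lab[, , d[3L]]))
  border_labels <- setdiff(border_labels, 0L)
  interior <- air & !(array(lab %in% border_labels, dim = d))
  if (!any(interior)) stop("no lung-like region found")
  idx <- which(interior, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2L, min) - 2L, 1L)
  hi <- pmin(apply(idx, 2L, max) + 2L, d)
  cropped <- volume$data[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L], drop = FALSE]
  out <- volume_image(cropped, spacing = volume$spacing,
                      origin = volume$origin + (lo - 1L) * volume$spacing)
  structure(list(volume = out, offset_voxels = as.integer(lo - 1L),
                 original_dim = d),
            class = "crop_result")
}

#' @export
print.crop_result <- function(x, ...) {
  cat(sprintf("<crop_result> %s -> %s voxels, offset (%s)\n",
              paste(x$original_dim, collapse = "x"),
              paste(dim(x$volume$data), collapse = "x"),
              paste(x$offset_voxels, collapse = ", ")))
  invisible(x)
}

#' Embed a cropped mask back into the original grid
#'
#' @param mask A [binary_mask()] on the cropped grid.
#' @param crop The [auto_crop()] result that produced the cropped grid.
#' @param original_origin Origin of the uncropped volume (mm).
#' @return A [binary_mask()] on the original grid.
#' @export
uncrop_mask <- function(mask, crop, original_origin = crop$volume$origin -
                          crop$offset_voxels * crop$volume$spacing) {
  d <- crop$original_dim
  out <- array(FALSE, dim = d)
  o <- crop$offset_voxels
  cd <- dim(mask$data)
  out[o[1L] + seq_len(cd[1L]), o[2L] + seq_len(cd[2L]), o[3L] + seq_len(cd[3L])] <-
    mask$data
  binary_mask(out, spacing = mask$spacing, origin = original_origin)
}

#' Per-voxel tube probability (multi-scale Hessian tube-likeness)
#'
#' Computes, at each scale, a Frangi-type tube-likeness measure from the
#' eigenvalues of the Gaussian-smoothed, gamma-normalised image Hessian,
#' oriented for tubes darker than their surroundings (airway lumen in CT).
#' The per-voxel value is the maximum response over scales, rescaled to
#' `[0, 1]` by the global maximum. Deterministic; invariant to adding a
#' constant to the whole volume.
#'
#' @param volume A [volume_image()].
#' @param radii_mm Scale set in mm; each must be at least the largest voxel
#'   spacing. The default spans trachea-to-subsegmental airway radii.
#' @param contrast_hu Intensity contrast (HU) between lumen and surroundings
#'   at which the structureness term saturates.
#' @param alpha,beta Frangi plate/blob discrimination parameters.
#' @return An object of class `tube_probability_map`: list with `data` (3D
#'   array in `[0, 1]`), `radii_mm`, `spacing`, `origin`.
#' @export
tube_probability <- function(volume, radii_mm = c(1.5, 2, 3, 4.5, 6),
                             contrast_hu = 150, alpha = 0.5, beta = 0.5) {
  stopifnot(inherits(volume, "volume_image"))
  radii_mm <- as.numeric(radii_mm)
  if (!length(radii_mm)) stop("`radii_mm` must be nonempty")
  if (any(radii_mm < max(volume$spacing)))
    stop(sprintf("scale %.3g mm is smaller than the voxel spacing %.3g mm",
                 min(radii_mm), max(volume$spacing)))
  d <- dim(volume$data)
  resp <- .cpp_tube_response(volume$data, d, volume$spacing, radii_mm,
                             alpha, beta, contrast_hu / 2)
  m <- max(resp)
  if (m > 0) resp <- resp / m
  structure(list(data = array(resp, dim = d), radii_mm = radii_mm,
                 spacing = volume$spacing, origin = volume$origin),
            class = "tube_probability_map")
}

#' @export
print.tube_probability_map <- function(x, ...) {
  cat(sprintf("<tube_probability_map> %s voxels, scales {%s} mm, max %.3f\n",
              paste(dim(x$data), collapse = "x"),
              paste(x$radii_mm, collapse = ", "), max(x$data)))
  invisible(x)
}
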