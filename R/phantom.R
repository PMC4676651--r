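# Synthetic branching-airway phantom: a dichotomous tree of capsules (dark
# lumen inside a brighter wall, embedded in lung-parenchyma-like background)
# with exact ground-truth centerline tree and EXACT09-style reference labels.

LBL_BACKGROUND <- 0L
LBL_CORRECT <- 1L
LBL_WRONG <- 2L
LBL_UNKNOWN <- 3L

#' Specify a synthetic airway phantom
#'
#' Defines the geometry and intensity model of a binary (dichotomous)
#' branching-airway phantom. The trachea (generation 1) runs cranio-caudally
#' and splits at a carina into two main bronchi (generation 2); each child is
#' rotated by `±branching_angle_deg` in planes that alternate between
#' generations. Radii and branch lengths taper geometrically per generation.
#'
#' @param generations Number of generations (>= 1), trachea = 1.
#' @param root_radius_mm Trachea lumen radius in mm.
#' @param radius_taper Per-generation radius multiplier in (0, 1).
#' @param branch_length_mm Either a scalar base length (mm) for the trachea,
#'   tapered by `length_taper` per generation, or a vector of per-generation
#'   lengths.
#' @param length_taper Per-generation length multiplier used when
#'   `branch_length_mm` is scalar.
#' @param branching_angle_deg Half-angle between a child and its parent's
#'   direction, degrees.
#' @param spacing_mm Voxel spacing, scalar or `(z, y, x)` vector, mm.
#' @param hu_lumen,hu_wall,hu_parenchyma Intensities (HU) of airway lumen,
#'   airway wall and background parenchyma. Must satisfy
#'   `hu_lumen < hu_parenchyma < hu_wall`.
#' @param wall_thickness_mm Airway wall thickness, mm.
#' @param noise_sigma_hu Standard deviation of additive i.i.d. Gaussian noise.
#' @param margin_mm Parenchyma margin around the tree's bounding box, mm.
#' @param seed Random seed (noise and any stochastic helpers).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(generations,
                         root_radius_mm = 9,
                         radius_taper = 0.7,
                         branch_length_mm = 30,
                         length_taper = 0.7,
                         branching_angle_deg = 35,
                         spacing_mm = 0.5,
                         hu_lumen = -1000,
                         hu_wall = 0,
                         hu_parenchyma = -850,
                         wall_thickness_mm = 1.5,
                         noise_sigma_hu = 0,
                         margin_mm = 4,
                         seed = 1L) {
  generations <- as.integer(generations)
  if (generations < 1L) stop("`generations` must be >= 1")
  if (radius_taper <= 0 || radius_taper >= 1)
    stop("`radius_taper` must lie in (0, 1)")
  spacing <- if (length(spacing_mm) == 1L) rep(spacing_mm, 3L) else as.numeric(spacing_mm)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("bad `spacing_mm`")
  if (!(hu_lumen < hu_parenchyma && hu_parenchyma < hu_wall))
    stop("need hu_lumen < hu_parenchyma < hu_wall")
  if (noise_sigma_hu < 0) stop("`noise_sigma_hu` must be >= 0")
  if (length(branch_length_mm) == 1L) {
    lengths <- branch_length_mm * length_taper^(seq_len(generations) - 1)
  } else {
    if (length(branch_length_mm) != generations)
      stop("`branch_length_mm` must be scalar or one length per generation")
    lengths <- as.numeric(branch_length_mm)
  }
  radii <- root_radius_mm * radius_taper^(seq_len(generations) - 1)
  bad <- which(radii < 2 * max(spacing))
  if (length(bad))
    stop(sprintf("tube unresolvable at generation %d: radius %.2f mm < 2 x max spacing %.2f mm",
                 bad[1L], radii[bad[1L]], max(spacing)))
  structure(list(generations = generations, root_radius_mm = root_radius_mm,
                 radius_taper = radius_taper, lengths_mm = lengths,
                 radii_mm = radii, branching_angle_deg = branching_angle_deg,
                 spacing_mm = spacing, hu_lumen = hu_lumen, hu_wall = hu_wall,
                 hu_parenchyma = hu_parenchyma,
                 wall_thickness_mm = wall_thickness_mm,
                 noise_sigma_hu = noise_sigma_hu, margin_mm = margin_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# analytic branch layout: one straight segment per branch, binary tree.
# Each branch carries an orthonormal frame; children rotate by +/- theta
# around alternating perpendiculars so successive bifurcation planes alternate.
phantom_segments <- function(spec) {
  theta <- spec$branching_angle_deg * pi / 180
  segs <- list()
  # frame vectors in (z, y, x); trachea points caudally (-z)
  queue <- list(list(start = c(0, 0, 0), d = c(-1, 0, 0), p1 = c(0, 1, 0),
                     p2 = c(0, 0, 1), gen = 1L, parent = NA_integer_))
  while (length(queue)) {
    b <- queue[[1L]]; queue <- queue[-1L]
    len <- spec$lengths_mm[b$gen]
    end <- b$start + len * b$d
    segs[[length(segs) + 1L]] <-
      list(start = b$start, end = end, radius = spec$radii_mm[b$gen],
           generation = b$gen, parent = b$parent)
    bi <- length(segs)
    if (b$gen < spec$generations) {
      for (sgn in c(1, -1)) {
        d_new <- cos(theta) * b$d + sgn * sin(theta) * b$p1
        d_new <- d_new / sqrt(sum(d_new^2))
        p1_new <- b$p2 - sum(b$p2 * d_new) * d_new
        p1_new <- p1_new / sqrt(sum(p1_new^2))
        p2_new <- c(d_new[2] * p1_new[3] - d_new[3] * p1_new[2],
                    d_new[3] * p1_new[1] - d_new[1] * p1_new[3],
                    d_new[1] * p1_new[2] - d_new[2] * p1_new[1])
        queue[[length(queue) + 1L]] <-
          list(start = end, d = d_new, p1 = p1_new, p2 = p2_new,
               gen = b$gen + 1L, parent = bi)
      }
    }
  }
  segs
}

#' Generate a synthetic airway phantom with ground truth
#'
#' Renders the branching tree defined by a [phantom_spec()] into a CT-like
#' volume (lumen capsules inside wall shells, embedded in parenchyma, plus
#' optional Gaussian noise), together with the ground-truth lumen mask, the
#' exact centerline tree (points sampled at most half a voxel apart along each
#' branch axis) and EXACT09-style reference labels (`correct` = lumen,
#' `unknown` = a one-voxel rind around the lumen, `wrong` = everything else,
#' with trachea and main-bronchus sub-masks).
#'
#' Deterministic for a fixed `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_bundle`: list with `volume`
#'   ([volume_image()]), `lumen_mask` ([binary_mask()]), `tree`
#'   ([centerline_tree()]), `labels` ([reference_labels()]) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  segs <- phantom_segments(spec)
  reach <- max(vapply(segs, function(s) s$radius, 1)) + spec$wall_thickness_mm
  allpts <- do.call(rbind, lapply(segs, function(s) rbind(s$start, s$end)))
  lo <- apply(allpts, 2L, min) - reach - spec$margin_mm
  hi <- apply(allpts, 2L, max) + reach + spec$margin_mm
  dims <- as.integer(ceiling((hi - lo) / spec$spacing_mm)) + 1L
  if (any(dims > 256L))
    stop("phantom does not fit in 256^3 voxels at the given spacing")
  origin <- lo
  segmat <- do.call(rbind, lapply(segs, function(s) c(s$start, s$end, s$radius,
                                                      spec$wall_thickness_mm)))
  rend <- .cpp_render_tree(dims, spec$spacing_mm, origin, segmat,
                           seq_along(segs), spec$hu_lumen, spec$hu_wall,
                           spec$hu_parenchyma)
  vol <- rend$volume
  if (spec$noise_sigma_hu > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(spec$seed)
    vol <- vol + array(rnorm(length(vol), 0, spec$noise_sigma_hu), dim = dims)
  }
  volume <- volume_image(array(vol, dim = dims), spacing = spec$spacing_mm,
                         origin = origin)
  lumen <- binary_mask(array(rend$lumen, dim = dims),
                       spacing = spec$spacing_mm, origin = origin)
  branch_id <- array(rend$branch_id, dim = dims)

  # ground-truth centerline: sample each branch axis at <= spacing/2 steps
  step <- min(spec$spacing_mm) / 2
  pts <- NULL
  branches <- list()
  end_id <- integer(length(segs))  # point id of each branch's last point
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    len <- sqrt(sum((s$end - s$start)^2))
    nseg <- max(1L, ceiling(len / step))
    tt <- seq(0, 1, length.out = nseg + 1L)
    p <- outer(tt, s$end - s$start) + matrix(s$start, nrow = length(tt),
                                             ncol = 3L, byrow = TRUE)
    if (is.na(s$parent)) {
      ids <- nrow_or0(pts) + seq_len(nrow(p))
      pts <- rbind(pts, p)
    } else {
      # share the junction point with the parent
      ids <- c(end_id[s$parent], nrow_or0(pts) + seq_len(nrow(p) - 1L))
      pts <- rbind(pts, p[-1L, , drop = FALSE])
    }
    end_id[i] <- ids[length(ids)]
    branches[[i]] <- list(point_ids = ids, generation = s$generation,
                          parent = s$parent)
  }
  tree <- centerline_tree(pts, branches, root_point = 1L)

  labels <- array(LBL_WRONG, dim = dims)
  rind <- array(.cpp_dilate26(lumen$data, dims), dim = dims) & !lumen$data
  labels[rind] <- LBL_UNKNOWN
  labels[lumen$data] <- LBL_CORRECT
  gens <- vapply(segs, function(s) s$generation, 1L)
  trachea <- binary_mask(array(branch_id %in% which(gens == 1L), dim = dims) & lumen$data,
                         spacing = spec$spacing_mm, origin = origin)
  mainbr <- binary_mask(array(branch_id %in% which(gens == 2L), dim = dims) & lumen$data,
                        spacing = spec$spacing_mm, origin = origin)
  ref <- reference_labels(labels, branch_id, trachea, mainbr,
                          spacing = spec$spacing_mm, origin = origin)
  structure(list(volume = volume, lumen_mask = lumen, tree = tree,
                 labels = ref, spec = spec),
            class = "phantom_bundle")
}

nrow_or0 <- function(x) if (is.null(x)) 0L else nrow(x)

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf("<phantom_bundle> %d generations, %d branches, grid %s\n",
              x$spec$generations, length(x$tree$branches),
              paste(dim(x$volume$data), collapse = " x ")))
  invisible(x)
}

#' Manufacture a known-imperfect segmentation from a phantom
#'
#' Starts from the ground-truth lumen mask, removes every branch of
#' generation greater than `drop_generations_above`, and attaches
#' `leak_blobs` random 26-connected blobs of `leak_voxels_each` voxels to the
#' airway surface, entirely outside the `correct` and `unknown` reference
#' regions. Blobs are pairwise non-adjacent so each one is a separate leakage
#' component.
#'
#' @param bundle A [generate_phantom()] result.
#' @param drop_generations_above Keep branches with generation up to this.
#' @param leak_blobs Number of leak blobs to attach.
#' @param leak_voxels_each Voxels per blob.
#' @param seed Random seed for blob placement.
#' @return A [binary_mask()].
#' @export
corrupt_segmentation <- function(bundle, drop_generations_above,
                                 leak_blobs = 0L, leak_voxels_each = 0L,
                                 seed = 1L) {
  stopifnot(inherits(bundle, "phantom_bundle"), drop_generations_above >= 1)
  dims <- dim(bundle$lumen_mask$data)
  gens <- vapply(bundle$tree$branches, function(b) b$generation, 1L)
  keep_ids <- which(gens <= drop_generations_above)
  bid <- bundle$labels$branch_id
  mask <- bundle$lumen_mask$data & array(bid %in% keep_ids, dim = dims)

  if (leak_blobs > 0L) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    lab <- bundle$labels$labels
    wrong <- lab == LBL_WRONG
    near <- array(.cpp_dilate26(array(lab != LBL_WRONG, dim = dims), dims),
                  dim = dims)
    starts_ok <- which(wrong & near)  # wrong voxels touching the unknown rind
    forbidden <- array(FALSE, dim = dims)
    nz <- dims[1L]; ny <- dims[2L]
    for (bi in seq_len(leak_blobs)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        cand <- setdiff(starts_ok, which(forbidden))
        if (!length(cand)) break
        start <- cand[sample.int(length(cand), 1L)]
        blob <- grow_blob(start, leak_voxels_each, wrong & !forbidden, dims)
        if (length(blob) == leak_voxels_each) {
          mask[blob] <- TRUE
          bm <- array(FALSE, dim = dims)
          bm[blob] <- TRUE
          forbidden <- forbidden | array(.cpp_dilate26(bm, dims), dim = dims)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place leak blob ", bi,
             " outside the correct/unknown regions")
    }
  }
  binary_mask(mask, spacing = bundle$lumen_mask$spacing,
              origin = bundle$lumen_mask$origin)
}

# random 26-connected blob of n voxels inside `allowed`, linear indices
grow_blob <- function(start, n, allowed, dims) {
  nz <- dims[1L]; ny <- dims[2L]; nx <- dims[3L]
  in_blob <- c(start)
  frontier <- neighbor26(start, dims)
  frontier <- frontier[allowed[frontier]]
  while (length(in_blob) < n && length(frontier)) {
    pick <- frontier[sample.int(length(frontier), 1L)]
    in_blob <- c(in_blob, pick)
    frontier <- setdiff(unique(c(frontier, neighbor26(pick, dims))),
                        in_blob)
    frontier <- frontier[allowed[frontier]]
  }
  in_blob
}

neighbor26 <- function(lin, dims) {
  nz <- dims[1L]; ny <- dims[2L]; nx <- dims[3L]
  p <- lin - 1L
  z <- p %% nz; r <- p %/% nz; y <- r %% ny; x <- r %/% ny
  off <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  off <- off[!(off$dz == 0 & off$dy == 0 & off$dx == 0), ]
  zz <- z + off$dz; yy <- y + off$dy; xx <- x + off$dx
  ok <- zz >= 0 & zz < nz & yy >= 0 & yy < ny & xx >= 0 & xx < nx
  (zz[ok] + nz * (yy[ok] + ny * xx[ok])) + 1L
}

#' Punch a hole through an airway wall
#'
#' Replaces wall voxels along a radial channel at the trachea's mid-point with
#' parenchyma intensity, creating the thin-wall defect through which naive
#' region growing leaks. Reference labels are left untouched, so leaked
#' voxels score as `wrong`.
#'
#' @param bundle A [generate_phantom()] result.
#' @param hole_radius_mm Channel radius, mm (default one voxel wide).
#' @return The bundle with a modified `volume`.
#' @export
punch_wall_hole <- function(bundle, hole_radius_mm = NULL) {
  stopifnot(inherits(bundle, "phantom_bundle"))
  spec <- bundle$spec
  if (is.null(hole_radius_mm)) hole_radius_mm <- max(spec$spacing_mm)
  segs <- phantom_segments(spec)
  s <- segs[[1L]]
  mid <- (s$start + s$end) / 2
  radial <- c(0, 1, 0)  # +y, perpendicular to the trachea axis
  r0 <- spec$radii_mm[1L]
  ts <- seq(r0 - hole_radius_mm,
            r0 + spec$wall_thickness_mm + max(spec$spacing_mm),
            by = min(spec$spacing_mm) / 2)
  chan <- t(vapply(ts, function(t) mid + t * radial, numeric(3)))
  dims <- dim(bundle$volume$data)
  hole <- array(.cpp_stamp_balls(dims, spec$spacing_mm, bundle$volume$origin,
                                 chan, hole_radius_mm), dim = dims)
  hole <- hole & bundle$volume$data > (spec$hu_parenchyma + spec$hu_wall) / 2  # wall only
  bundle$volume$data[hole] <- spec$hu_parenchyma
  bundle
}
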