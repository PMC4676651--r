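# Centerline extraction: either from the tube-probability map (pipeline
# route) or by thinning a binary mask (the route used for masks coming from
# threshold-based segmentations). Both reduce a 26-connected voxel set to a
# one-voxel-wide, topology-preserving skeleton, link the skeleton voxels into
# a graph, root it at the maximal-z endpoint (cranial trachea) and decompose
# it into branches with generations.

#' Extract a centerline tree from a tube-probability map
#'
#' Selects voxels with probability at or above `probability_threshold` whose
#' intensity lies in the airway-lumen air window (below `hu_air_max`), keeps
#' the largest 26-connected component (the airway component that includes the
#' trachea top), thins it to a skeleton, links the skeleton into a rooted
#' tree in world coordinates, prunes spurs and assigns generations.
#'
#' The air window is what separates true lumen from the dark parenchymal
#' channels that also excite a curvature-based tube filter (the wedge of
#' near-air tissue between two sibling airway walls is locally
#' tube-shaped); tube-likeness alone cannot tell the two apart.
#'
#' @param tpm A [tube_probability_map()] result.
#' @param volume The [volume_image()] the map was computed from.
#' @param probability_threshold Selection threshold in (0, 1).
#' @param hu_air_max Upper intensity bound (HU) for candidate voxels; `Inf`
#'   disables the air window.
#' @param prune_mm Spur-prune length; default twice the mean voxel spacing.
#' @return A [centerline_tree()].
#' @export
extract_centerline <- function(tpm, volume, probability_threshold = 0.5,
                               hu_air_max = -925, prune_mm = NULL) {
  stopifnot(inherits(tpm, "tube_probability_map"),
            inherits(volume, "volume_image"))
  if (probability_threshold <= 0 || probability_threshold >= 1)
    stop("`probability_threshold` must lie in (0, 1)")
  d <- dim(tpm$data)
  if (!identical(d, dim(volume$data)))
    stop("probability map and volume grids differ")
  sel <- tpm$data >= probability_threshold
  if (!any(sel)) stop("no airway candidate: no voxel reaches the threshold")
  sel <- sel & volume$data < hu_air_max
  if (!any(sel)) stop("no airway candidate: no dark voxel reaches the threshold")
  comp <- largest_component(sel, d)
  radius_mask <- if (is.finite(hu_air_max)) {
    array(volume$data < hu_air_max, dim = d)
  } else NULL
  skeleton_to_tree(comp, tpm$spacing, tpm$origin, prune_mm = prune_mm,
                   radius_mask = radius_mask)
}

#' Extract a centerline tree by thinning a binary mask
#'
#' Topology-preserving 3D thinning of the largest 26-connected component of
#' the mask, followed by the same linking, rooting, spur pruning and branch
#' decomposition as [extract_centerline()].
#'
#' @param mask A [binary_mask()] with at least one foreground voxel.
#' @param prune_mm Spur-prune length; default twice the mean voxel spacing.
#' @return A [centerline_tree()].
#' @export
thinning_centerline <- function(mask, prune_mm = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) stop("mask is empty")
  d <- dim(mask$data)
  comp <- largest_component(mask$data, d)
  skeleton_to_tree(comp, mask$spacing, mask$origin, prune_mm = prune_mm)
}

largest_component <- function(mask, d) {
  lab <- .cpp_label_components(mask, d, 26L)
  tab <- tabulate(lab[lab > 0L])
  array(lab == which.max(tab), dim = d)
}

# Fill interior cavities (background components not reaching the volume
# border). A single enclosed background voxel would otherwise force the
# topology-preserving thinning to keep a closed shell around it.
fill_cavities <- function(mask) {
  d <- dim(mask)
  bg <- array(.cpp_label_components(!mask, d, 6L), dim = d)
  border <- unique(c(bg[c(1L, d[1L]), , ], bg[, c(1L, d[2L]), ],
                     bg[, , c(1L, d[3L])]))
  mask | !(array(bg %in% setdiff(border, 0L), dim = d) | mask)
}

# thin + link + root + prune; the shared back half of both centerline routes
skeleton_to_tree <- function(comp, spacing, origin, prune_mm = NULL,
                             radius_mask = NULL) {
  d <- dim(comp)
  if (is.null(prune_mm)) prune_mm <- 2 * mean(spacing)
  # one-voxel morphological closing seals the small handles and pits of a
  # bumpy threshold isosurface, which thinning would otherwise preserve as
  # skeleton loops; cavity filling removes enclosed background pockets
  comp <- array(.cpp_dilate26(comp, d), dim = d)
  comp <- !array(.cpp_dilate26(!comp, d), dim = d)
  comp <- fill_cavities(comp)
  skel <- array(.cpp_thin3d(comp, d), dim = d)
  idx <- which(skel)
  coords <- arrayInd(idx, d)  # (z, y, x), 1-based
  np <- length(idx)
  if (np == 1L) {
    pts <- voxel_to_world(coords, spacing, origin)
    return(centerline_tree(pts, list(list(point_ids = 1L, generation = 1L,
                                          parent = NA_integer_))))
  }
  # 26-neighbour adjacency by linear-index lookup
  nz <- d[1L]; ny <- d[2L]; nx <- d[3L]
  lut <- integer(prod(d))
  lut[idx] <- seq_len(np)
  off <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  off <- off[!(off$dz == 0 & off$dy == 0 & off$dx == 0), ]
  edges <- NULL
  for (i in seq_len(nrow(off))) {
    zz <- coords[, 1L] + off$dz[i]
    yy <- coords[, 2L] + off$dy[i]
    xx <- coords[, 3L] + off$dx[i]
    ok <- zz >= 1L & zz <= nz & yy >= 1L & yy <= ny & xx >= 1L & xx <= nx
    lin <- (zz[ok] - 1L) + nz * ((yy[ok] - 1L) + ny * (xx[ok] - 1L)) + 1L
    nb <- lut[lin]
    src <- which(ok)[nb > 0L]
    nb <- nb[nb > 0L]
    keep <- src < nb
    if (any(keep)) edges <- rbind(edges, cbind(src[keep], nb[keep]))
  }
  edges <- unique(edges)
  pts <- voxel_to_world(coords, spacing, origin)
  # root: endpoint (graph degree <= 1) with maximal z; fall back to global
  # max z if the skeleton has no endpoint
  deg <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = np)
  cand <- which(deg <= 1L)
  if (!length(cand)) cand <- seq_len(np)
  root <- cand[which.max(pts[cand, 1L])]
  # break incidental 26-adjacency cycles with a BFS spanning tree
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < np) g <- igraph::add_vertices(g, np - igraph::vcount(g))
  bf <- igraph::bfs(g, root = root, father = TRUE, unreachable = FALSE)
  father <- as.integer(bf$father)
  span <- cbind(seq_len(np), father)
  span <- span[!is.na(father) & father > 0L, , drop = FALSE]
  tree <- build_tree_from_edges(pts, span, root)
  tree <- prune_spurs(tree, prune_mm)
  # Local tube radii for spur pruning are measured on the physical air
  # lumen when available: the thresholded response core is systematically
  # slimmer than the airway and would underestimate the artifact scale.
  if (is.null(radius_mask)) radius_mask <- comp
  tree <- prune_junction_spurs(tree, radius_mask, spacing, origin)
  tree <- trim_terminal_tails(tree, radius_mask, spacing, origin)
  tree <- smooth_tree_points(tree)
  validate_centerline_tree(tree)
  tree
}

# A skeleton runs past the end of a blunt or rounded tube into the cap,
# where the inscribed radius shrinks towards the surface. The natural
# endpoint of a tube's centerline is the centre of the last maximal
# inscribed sphere: walk inward from each free tip while the inscribed
# radius still increases, and drop the points beyond it.
trim_terminal_tails <- function(tree, comp, spacing, origin,
                                tol = max(spacing) / 2) {
  r_at <- function(pid) local_tube_radius(tree$points[pid, ], comp, spacing,
                                          origin)
  nb <- length(tree$branches)
  parents <- vapply(tree$branches, function(b)
    if (is.na(b$parent)) 0L else b$parent, 1L)
  has_child <- seq_len(nb) %in% parents
  changed <- FALSE
  for (i in seq_len(nb)) {
    b <- tree$branches[[i]]
    ids <- b$point_ids
    n <- length(ids)
    if (n < 3L) next
    # terminal tip at the branch end
    if (!has_child[i]) {
      k <- n
      while (k > 2L && r_at(ids[k - 1L]) > r_at(ids[k]) + tol) k <- k - 1L
      if (k < n) {
        tree$branches[[i]]$point_ids <- ids[seq_len(k)]
        changed <- TRUE
      }
    }
    # the root branch has a free tip at its start
    if (is.na(b$parent)) {
      ids <- tree$branches[[i]]$point_ids
      n <- length(ids)
      k <- 1L
      while (k < n - 1L && r_at(ids[k + 1L]) > r_at(ids[k]) + tol) k <- k + 1L
      if (k > 1L) {
        tree$branches[[i]]$point_ids <- ids[k:n]
        tree$root_point <- ids[k]
        changed <- TRUE
      }
    }
  }
  if (!changed) return(tree)
  compact_tree(centerline_tree(tree$points, tree$branches,
                               root_point = tree$root_point, validate = FALSE))
}

# Radius-adaptive spur removal. Thinning a thick tube grows short skeleton
# twigs inside every junction blob and a "crow's foot" of legs at blunt tube
# ends; their length scales with the local tube radius, so a fixed prune
# length cannot separate them from real terminal branches. A terminal branch
# whose chord (straight start-to-tip distance; cap legs curve, so chord is
# the robust measure) is shorter than `factor` times its parent branch's
# tube radius is such an artifact. A short single-child root stub (the
# crow's foot at the cranial end) is removed symmetrically, re-rooting at
# its child.
prune_junction_spurs <- function(tree, comp, spacing, origin, factor = 1.7) {
  # robust tube radius of a branch: median of per-point inscribed radii
  # over the middle third of the branch, away from the inflated radii
  # inside the junction blobs at either end
  branch_radius <- function(tree, i) {
    ids <- tree$branches[[i]]$point_ids
    n <- length(ids)
    mid <- ids[max(1L, ceiling(n / 3)):max(1L, n - floor(n / 3))]
    stats::median(vapply(mid, function(pid)
      local_tube_radius(tree$points[pid, ], comp, spacing, origin), 1))
  }
  chord <- function(tree, i) {
    ids <- tree$branches[[i]]$point_ids
    sqrt(sum((tree$points[ids[length(ids)], ] - tree$points[ids[1L], ])^2))
  }
  repeat {
    nb <- length(tree$branches)
    if (nb <= 1L) break
    parents <- vapply(tree$branches, function(b)
      if (is.na(b$parent)) 0L else b$parent, 1L)
    has_child <- seq_len(nb) %in% parents
    drop <- integer(0)
    rad_cache <- rep(NA_real_, nb)
    for (i in seq_len(nb)) {
      b <- tree$branches[[i]]
      if (has_child[i] || is.na(b$parent)) next
      if (is.na(rad_cache[b$parent]))
        rad_cache[b$parent] <- branch_radius(tree, b$parent)
      if (chord(tree, i) < factor * rad_cache[b$parent]) drop <- c(drop, i)
    }
    # root-side stub: a short single-child root branch is the surviving leg
    # of a crow's foot at the cranial tube end; remove and re-root
    new_root <- tree$root_point
    ri <- which(vapply(tree$branches, function(b) is.na(b$parent), TRUE))
    root_children <- setdiff(which(parents == ri), drop)
    if (length(root_children) == 1L && !(ri %in% drop)) {
      r_child <- branch_radius(tree, root_children)
      if (chord(tree, ri) < factor * r_child) {
        drop <- c(drop, ri)
        rb <- tree$branches[[ri]]
        new_root <- rb$point_ids[length(rb$point_ids)]
      }
    }
    if (!length(drop)) break
    keep <- setdiff(seq_len(nb), drop)
    kept_edges <- tree_edges(
      structure(list(points = tree$points, branches = tree$branches[keep],
                     root_point = new_root), class = "centerline_tree"))
    tree <- compact_tree(build_tree_from_edges(tree$points, kept_edges,
                                               new_root))
  }
  tree
}

# Light polyline smoothing: two passes of a 3-point moving average on
# interior points (endpoints and junctions stay fixed). Removes the
# staircase length inflation of voxel skeletons.
smooth_tree_points <- function(tree, passes = 2L) {
  fixed <- rep(FALSE, nrow(tree$points))
  for (b in tree$branches) {
    ids <- b$point_ids
    fixed[ids[1L]] <- TRUE
    fixed[ids[length(ids)]] <- TRUE
  }
  pts <- tree$points
  for (k in seq_len(passes)) {
    new_pts <- pts
    for (b in tree$branches) {
      ids <- b$point_ids
      n <- length(ids)
      if (n < 3L) next
      interior <- ids[2:(n - 1L)]
      avg <- (pts[ids[1:(n - 2L)], , drop = FALSE] +
                pts[interior, , drop = FALSE] +
                pts[ids[3:n], , drop = FALSE]) / 3
      move <- !fixed[interior]
      new_pts[interior[move], ] <- avg[move, , drop = FALSE]
    }
    pts <- new_pts
  }
  centerline_tree(pts, tree$branches, root_point = tree$root_point,
                  validate = FALSE)
}

# distance (mm) from a world point to the nearest background voxel,
# by expanding box search on the component mask
local_tube_radius <- function(point, comp, spacing, origin) {
  d <- dim(comp)
  v <- world_to_voxel(point, spacing, origin)[1L, ]
  v <- pmin(pmax(v, 1L), d)
  maxr <- ceiling(30 / min(spacing))
  for (r in seq_len(maxr)) {
    lo <- pmax(v - r, 1L)
    hi <- pmin(v + r, d)
    sub <- comp[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L], drop = FALSE]
    if (!all(sub)) {
      bg <- which(!sub, arr.ind = TRUE)
      off <- sweep(bg, 2L, v - lo + 1L, "-")
      return(min(sqrt(colSums((t(off) * spacing)^2))))
    }
    if (all(lo == 1L) && all(hi == d)) break
  }
  Inf
}
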