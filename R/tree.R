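# Centerline trees: rooted acyclic graphs of 3D world points (mm, z/y/x
# columns) decomposed into branches. The trachea is generation 1, the main
# bronchi generation 2, and every bifurcation increments the generation.

#' Construct a centerline tree
#'
#' @param points Numeric matrix, one row per point, columns `(z, y, x)` in mm.
#' @param branches List of branches; each branch is a list with `point_ids`
#'   (ordered indices into `points`), `generation` (int, root = 1) and
#'   `parent` (branch index or `NA` for the root branch). `length_mm` is
#'   recomputed.
#' @param root_point Index of the root point (cranial end of the trachea).
#' @param validate Check the tree invariants (connected, acyclic, generations
#'   consistent, branches chained at shared junction points).
#' @return An object of class `centerline_tree`.
#' @export
centerline_tree <- function(points, branches, root_point = 1L, validate = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("`points` must have 3 columns (z, y, x)")
  colnames(points) <- c("z", "y", "x")
  branches <- lapply(branches, function(b) {
    b$point_ids <- as.integer(b$point_ids)
    b$generation <- as.integer(b$generation)
    b$parent <- if (is.null(b$parent) || is.na(b$parent)) NA_integer_ else as.integer(b$parent)
    b$length_mm <- polyline_length(points[b$point_ids, , drop = FALSE])
    b
  })
  tree <- structure(list(points = points, branches = branches,
                         root_point = as.integer(root_point)),
                    class = "centerline_tree")
  if (validate) validate_centerline_tree(tree)
  tree
}

polyline_length <- function(p) {
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Validate centerline tree invariants
#'
#' Checks connectivity, acyclicity, generation bookkeeping (root branch has
#' generation 1, children increment by 1) and that every non-root branch
#' starts at its parent's last point. Stops with an informative error on the
#' first violation.
#'
#' @param tree A [centerline_tree()].
#' @return Invisibly `TRUE`.
#' @export
validate_centerline_tree <- function(tree) {
  stopifnot(inherits(tree, "centerline_tree"))
  np <- nrow(tree$points)
  if (np < 1L) stop("tree has no points")
  if (length(tree$branches) < 1L) stop("tree has no branches")
  edges <- tree_edges(tree)
  used <- sort(unique(c(tree$root_point, as.vector(edges))))
  if (!all(used >= 1L & used <= np)) stop("branch point ids out of range")
  if (np > 1L) {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, np - igraph::vcount(g)))
    if (igraph::components(g)$no != 1L) stop("tree is not connected")
    if (nrow(edges) != np - 1L) stop("tree has a cycle or duplicate edges")
  }
  roots <- which(vapply(tree$branches, function(b) is.na(b$parent), TRUE))
  if (length(roots) != 1L) stop("tree must have exactly one root branch")
  for (i in seq_along(tree$branches)) {
    b <- tree$branches[[i]]
    if (length(b$point_ids) < 1L) stop("empty branch ", i)
    if (is.na(b$parent)) {
      if (b$generation != 1L) stop("root branch must be generation 1")
      if (b$point_ids[1L] != tree$root_point)
        stop("root branch must start at the root point")
    } else {
      pb <- tree$branches[[b$parent]]
      if (b$generation != pb$generation + 1L)
        stop("branch ", i, ": generation must be parent's + 1")
      if (b$point_ids[1L] != pb$point_ids[length(pb$point_ids)])
        stop("branch ", i, ": must start at its parent's last point")
    }
    if (b$length_mm < 0) stop("negative branch length")
  }
  invisible(TRUE)
}

# unique undirected edge list (2-column matrix of point ids)
tree_edges <- function(tree) {
  el <- lapply(tree$branches, function(b) {
    ids <- b$point_ids
    if (length(ids) < 2L) return(NULL)
    cbind(ids[-length(ids)], ids[-1L])
  })
  el <- do.call(rbind, el)
  if (is.null(el)) return(matrix(integer(), ncol = 2L))
  el <- t(apply(el, 1L, sort))
  unique(el)
}

#' @export
print.centerline_tree <- function(x, ...) {
  gens <- vapply(x$branches, function(b) b$generation, 1L)
  cat(sprintf("<centerline_tree> %d points, %d branches, %d generations, total length %.1f mm\n",
              nrow(x$points), length(x$branches), max(gens),
              sum(vapply(x$branches, function(b) b$length_mm, 1))))
  invisible(x)
}

#' @export
summary.centerline_tree <- function(object, ...) {
  h <- branches_per_generation(object)
  print(object)
  print(h)
  invisible(h)
}

# Decompose a rooted spanning tree (edge list over point ids) into maximal
# branches between junction/terminal points, assigning generations from the
# root. Children are visited in ascending point-id order for determinism.
build_tree_from_edges <- function(points, edges, root_point) {
  np <- nrow(points)
  if (np == 1L || nrow(edges) == 0L) {
    return(centerline_tree(points,
                           list(list(point_ids = root_point, generation = 1L,
                                     parent = NA_integer_)),
                           root_point = root_point, validate = FALSE))
  }
  adj <- vector("list", np)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj <- lapply(adj, function(v) sort(unique(v)))
  parent <- integer(np); parent[] <- -1L
  parent[root_point] <- 0L
  order_bfs <- integer(0)
  q <- c(root_point)
  while (length(q)) {
    v <- q[[1L]]; q <- q[-1L]
    order_bfs <- c(order_bfs, v)
    for (w in adj[[v]]) if (parent[w] == -1L) {
      parent[w] <- v
      q <- c(q, w)
    }
  }
  children <- vector("list", np)
  for (v in order_bfs) if (parent[v] > 0L)
    children[[parent[v]]] <- c(children[[parent[v]]], v)
  children <- lapply(children, sort)

  branches <- list()
  # stack frames: initial point-id run of the branch + parent branch index
  stack <- list(list(ids0 = root_point, parent = NA_integer_))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    ids <- fr$ids0
    v <- ids[[length(ids)]]
    repeat {
      ch <- children[[v]]
      if (length(ch) != 1L) break
      v <- ch[[1L]]
      ids <- c(ids, v)
    }
    gen <- if (is.na(fr$parent)) 1L else branches[[fr$parent]]$generation + 1L
    branches[[length(branches) + 1L]] <-
      list(point_ids = ids, generation = gen, parent = fr$parent)
    bi <- length(branches)
    for (ch in rev(children[[v]]))
      stack[[length(stack) + 1L]] <- list(ids0 = c(v, ch), parent = bi)
  }
  centerline_tree(points, branches, root_point = root_point, validate = FALSE)
}

#' Prune short terminal branches (spurs)
#'
#' Iteratively removes terminal branches shorter than `min_length_mm`, then
#' re-merges pass-through junctions and recomputes generations. Idempotent at
#' a fixed `min_length_mm`. The root branch is never removed.
#'
#' @param tree A [centerline_tree()].
#' @param min_length_mm Minimum terminal branch length to keep (mm).
#' @return A pruned [centerline_tree()].
#' @export
prune_spurs <- function(tree, min_length_mm) {
  stopifnot(inherits(tree, "centerline_tree"), min_length_mm >= 0)
  if (min_length_mm == 0) return(tree)
  repeat {
    nb <- length(tree$branches)
    if (nb <= 1L) break
    parents <- vapply(tree$branches, function(b)
      if (is.na(b$parent)) 0L else b$parent, 1L)
    has_child <- seq_len(nb) %in% parents
    lens <- vapply(tree$branches, function(b) b$length_mm, 1)
    drop <- which(!has_child & lens < min_length_mm &
                    vapply(tree$branches, function(b) !is.na(b$parent), TRUE))
    if (!length(drop)) break
    keep <- setdiff(seq_len(nb), drop)
    kept_edges <- tree_edges(
      structure(list(points = tree$points, branches = tree$branches[keep],
                     root_point = tree$root_point), class = "centerline_tree"))
    tree <- compact_tree(build_tree_from_edges(tree$points, kept_edges,
                                               tree$root_point))
  }
  tree
}

# drop points not referenced by any branch and reindex
compact_tree <- function(tree) {
  used <- sort(unique(unlist(lapply(tree$branches, `[[`, "point_ids"))))
  if (length(used) == nrow(tree$points)) return(tree)
  remap <- integer(nrow(tree$points))
  remap[used] <- seq_along(used)
  branches <- lapply(tree$branches, function(b) {
    b$point_ids <- remap[b$point_ids]
    b
  })
  centerline_tree(tree$points[used, , drop = FALSE], branches,
                  root_point = remap[tree$root_point], validate = FALSE)
}

#' Restrict a tree to a maximum generation
#'
#' Keeps only branches with generation at or below `max_generation`; the
#' companion of [corrupt_segmentation()] for building known-imperfect
#' candidate trees.
#'
#' @param tree A [centerline_tree()].
#' @param max_generation Highest generation to keep (>= 1).
#' @return A [centerline_tree()].
#' @export
truncate_tree <- function(tree, max_generation) {
  stopifnot(inherits(tree, "centerline_tree"), max_generation >= 1)
  keep <- which(vapply(tree$branches, function(b)
    b$generation <= max_generation, TRUE))
  sub <- structure(list(points = tree$points, branches = tree$branches[keep],
                        root_point = tree$root_point),
                   class = "centerline_tree")
  out <- compact_tree(build_tree_from_edges(tree$points, tree_edges(sub),
                                            tree$root_point))
  validate_centerline_tree(out)
  out
}
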