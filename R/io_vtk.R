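# VTK legacy ASCII polydata I/O for centerline trees: POINTS in world mm
# (written x y z), one LINES polyline per branch, and a POINT_DATA scalar
# "generation" carrying each branch's generation index.

#' Write a centerline tree as VTK legacy polydata
#'
#' @param tree A [centerline_tree()]; must be nonempty.
#' @param path Output `.vtk` path.
#' @return Invisibly, `path`.
#' @export
write_centerline_polydata <- function(tree, path) {
  if (!inherits(tree, "centerline_tree") || nrow(tree$points) < 1L)
    stop("cannot write an empty centerline tree")
  np <- nrow(tree$points)
  gen_of_point <- rep(NA_integer_, np)
  for (b in tree$branches) {
    ids <- b$point_ids
    # junction points shared with the parent keep the parent's generation
    take <- is.na(gen_of_point[ids])
    gen_of_point[ids[take]] <- b$generation
  }
  gen_of_point[is.na(gen_of_point)] <- 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "airway centerline tree",
               "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", np)), con)
  # internal (z, y, x) -> VTK (x, y, z)
  writeLines(sprintf("%.6f %.6f %.6f",
                     tree$points[, 3L], tree$points[, 2L], tree$points[, 1L]),
             con)
  sizes <- vapply(tree$branches, function(b) length(b$point_ids), 1L)
  writeLines(sprintf("LINES %d %d", length(sizes), sum(sizes) + length(sizes)),
             con)
  for (b in tree$branches)
    writeLines(paste(c(length(b$point_ids), b$point_ids - 1L), collapse = " "),
               con)
  writeLines(c(sprintf("POINT_DATA %d", np),
               "SCALARS generation int 1",
               "LOOKUP_TABLE default",
               paste(gen_of_point)), con)
  invisible(path)
}

#' Read a centerline tree from VTK legacy polydata
#'
#' Parses a legacy ASCII polydata file with `POINTS` and `LINES`, rebuilds the
#' branch graph, and re-roots the tree at the point with the maximum z
#' coordinate (the cranial end of the trachea). Generations are recomputed
#' from the root.
#'
#' @param path Path to a `.vtk` legacy ASCII polydata file.
#' @return A [centerline_tree()].
#' @export
read_centerline_polydata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5L || !any(grepl("^DATASET\\s+POLYDATA", lines)))
    stop("not a VTK legacy polydata file: ", path)
  toks <- scan_tokens <- unlist(strsplit(paste(lines[-(1:2)], collapse = "\n"),
                                         "[ \t\n\r]+"))
  toks <- toks[nzchar(toks)]
  ip <- which(toupper(toks) == "POINTS")
  if (!length(ip)) stop("polydata lacks POINTS")
  ip <- ip[[1L]]
  np <- as.integer(toks[ip + 1L])
  coords <- as.numeric(toks[(ip + 3L):(ip + 2L + 3L * np)])
  xyz <- matrix(coords, ncol = 3L, byrow = TRUE)
  points <- cbind(z = xyz[, 3L], y = xyz[, 2L], x = xyz[, 1L])
  il <- which(toupper(toks) == "LINES")
  if (!length(il)) stop("polydata lacks LINES; not a centerline file")
  il <- il[[1L]]
  ncell <- as.integer(toks[il + 1L])
  total <- as.integer(toks[il + 2L])
  body <- as.integer(toks[(il + 3L):(il + 2L + total)])
  polylines <- list()
  pos <- 1L
  for (i in seq_len(ncell)) {
    cnt <- body[pos]
    polylines[[i]] <- body[(pos + 1L):(pos + cnt)] + 1L
    pos <- pos + cnt + 1L
  }
  edges <- do.call(rbind, lapply(polylines, function(ids) {
    if (length(ids) < 2L) return(NULL)
    cbind(ids[-length(ids)], ids[-1L])
  }))
  if (is.null(edges)) edges <- matrix(integer(), ncol = 2L)
  if (nrow(edges)) {
    edges <- unique(t(apply(edges, 1L, sort)))
  }
  root <- which.max(points[, "z"])
  tree <- build_tree_from_edges(points, edges, root)
  validate_centerline_tree(tree)
  tree
}
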