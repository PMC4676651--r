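# Brute-force reference implementations of the evaluation formulas, written
# with plain loops over voxels/points, independent of the package internals.

oracle_overlap_counts <- function(seg, ref) {
  d <- dim(seg$data)
  Nc <- 0L; Nw <- 0L
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    if (!seg$data[z, y, x]) next
    if (ref$trachea_mask$data[z, y, x]) next
    if (ref$main_bronchi_mask$data[z, y, x]) next
    lb <- ref$labels[z, y, x]
    if (lb == 1L) Nc <- Nc + 1L
    if (lb == 2L) Nw <- Nw + 1L
  }
  c(Nc = Nc, Nw = Nw)
}

oracle_branch_detection <- function(seg_tree, ref, ref_tree) {
  d <- dim(ref$labels)
  gens <- sapply(ref_tree$branches, function(b) b$generation)
  eval_ids <- which(gens != 1L)
  hit <- rep(FALSE, length(ref_tree$branches))
  if (!is.null(seg_tree)) {
    for (i in seq_len(nrow(seg_tree$points))) {
      p <- seg_tree$points[i, ]
      v <- round((p - ref$origin) / ref$spacing) + 1
      if (any(v < 1) || any(v > d)) next
      b <- ref$branch_id[v[1], v[2], v[3]]
      if (b > 0L) hit[b] <- TRUE
    }
  }
  Nseg <- sum(hit[eval_ids])
  list(Nseg = Nseg, Nref = length(eval_ids),
       pct = if (length(eval_ids)) Nseg / length(eval_ids) * 100 else 0)
}

oracle_tree_length_detected <- function(seg, ref_tree, ref) {
  d <- dim(seg$data)
  inseg <- function(p) {
    v <- round((p - ref$origin) / ref$spacing) + 1
    if (any(v < 1) || any(v > d)) return(FALSE)
    seg$data[v[1], v[2], v[3]]
  }
  Lref <- 0; Lseg <- 0
  for (b in ref_tree$branches) {
    if (b$generation == 1L) next
    ids <- b$point_ids
    for (k in seq_len(length(ids) - 1L)) {
      p1 <- ref_tree$points[ids[k], ]; p2 <- ref_tree$points[ids[k + 1L], ]
      len <- sqrt(sum((p2 - p1)^2))
      Lref <- Lref + len
      if (inseg(p1) && inseg(p2)) Lseg <- Lseg + len
    }
  }
  list(Lseg_cm = Lseg / 10, Lref_cm = Lref / 10, pct = Lseg / Lref * 100)
}

# flood-fill leakage count on wrong-labelled seg voxels, 26-connectivity
oracle_leakage_stats <- function(seg, ref) {
  d <- dim(seg$data)
  wrong <- seg$data & ref$labels == 2L
  seen <- array(FALSE, dim = d)
  count <- 0L
  idx <- which(wrong, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list(count = 0L, volume_mm3 = 0))
  for (i in seq_len(nrow(idx))) {
    v0 <- idx[i, ]
    if (seen[v0[1], v0[2], v0[3]]) next
    count <- count + 1L
    stack <- list(v0)
    seen[v0[1], v0[2], v0[3]] <- TRUE
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (!dz && !dy && !dx) next
        w <- v + c(dz, dy, dx)
        if (any(w < 1) || any(w > d)) next
        if (wrong[w[1], w[2], w[3]] && !seen[w[1], w[2], w[3]]) {
          seen[w[1], w[2], w[3]] <- TRUE
          stack[[length(stack) + 1L]] <- w
        }
      }
    }
  }
  list(count = count, volume_mm3 = sum(wrong) * prod(ref$spacing))
}

# dense-subvoxel estimate of the capsule-union volume of a phantom spec
oracle_capsule_volume <- function(spec, samples_per_voxel = 3L) {
  segs <- airtree:::phantom_segments(spec)
  allp <- do.call(rbind, lapply(segs, function(s) rbind(s$start, s$end)))
  rmax <- max(sapply(segs, function(s) s$radius))
  lo <- apply(allp, 2, min) - rmax
  hi <- apply(allp, 2, max) + rmax
  h <- min(spec$spacing_mm) / samples_per_voxel
  gz <- seq(lo[1], hi[1], by = h)
  gy <- seq(lo[2], hi[2], by = h)
  gx <- seq(lo[3], hi[3], by = h)
  inside_n <- 0
  Y <- matrix(gy, length(gy), length(gx))
  X <- matrix(gx, length(gy), length(gx), byrow = TRUE)
  # slice-wise, vectorised point-to-segment distance per capsule
  for (z in gz) {
    inside <- matrix(FALSE, length(gy), length(gx))
    for (s in segs) {
      if (z < min(s$start[1], s$end[1]) - s$radius ||
          z > max(s$start[1], s$end[1]) + s$radius) next
      v <- s$end - s$start
      tt <- ((z - s$start[1]) * v[1] + (Y - s$start[2]) * v[2] +
               (X - s$start[3]) * v[3]) / sum(v * v)
      tt <- pmin(pmax(tt, 0), 1)
      dz <- z - (s$start[1] + tt * v[1])
      dy <- Y - (s$start[2] + tt * v[2])
      dx <- X - (s$start[3] + tt * v[3])
      inside <- inside | (dz * dz + dy * dy + dx * dx <= s$radius^2)
    }
    inside_n <- inside_n + sum(inside)
  }
  inside_n * h^3
}
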