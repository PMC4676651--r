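# Shared fixtures: phantoms are generated in code, cached per session.

.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(generations, noise_sigma_hu = 0, seed = 1L, ...) {
  key <- paste(generations, noise_sigma_hu, seed,
               paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.phantom_cache[[key]])) {
    .phantom_cache[[key]] <- generate_phantom(
      phantom_spec(generations, noise_sigma_hu = noise_sigma_hu,
                   seed = seed, ...))
  }
  .phantom_cache[[key]]
}

# compact phantom fitting a <= 32^3 grid, for brute-force oracle comparisons
mini_spec <- function(generations = 2L, seed = 1L, ...) {
  phantom_spec(generations, root_radius_mm = 2, radius_taper = 0.75,
               branch_length_mm = 5, length_taper = 0.8,
               wall_thickness_mm = 1, margin_mm = 1.5, seed = seed, ...)
}

mini_phantom <- function(generations = 2L, seed = 1L, ...) {
  key <- paste("mini", generations, seed,
               paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- generate_phantom(mini_spec(generations, seed, ...))
  .phantom_cache[[key]]
}

# straight-tube volume (no phantom machinery): cylinder along z
straight_tube_volume <- function(radius_mm = 4, length_mm = 40,
                                 spacing = 0.5, margin_mm = 6,
                                 hu_lumen = -1000, hu_wall = 0,
                                 hu_parenchyma = -850, wall_mm = 1.5) {
  half <- radius_mm + wall_mm + margin_mm
  nz <- ceiling((length_mm + 2 * margin_mm) / spacing) + 1L
  nyx <- ceiling(2 * half / spacing) + 1L
  vol <- array(hu_parenchyma, dim = c(nz, nyx, nyx))
  cy <- (nyx + 1) / 2
  z0 <- ceiling(margin_mm / spacing) + 1L
  z1 <- z0 + round(length_mm / spacing)
  yy <- matrix(seq_len(nyx), nyx, nyx)
  xx <- t(yy)
  r <- sqrt((yy - cy)^2 + (xx - cy)^2) * spacing
  wall_slice <- r <= radius_mm + wall_mm
  lumen_slice <- r <= radius_mm
  for (z in z0:z1) {
    sl <- vol[z, , ]
    sl[wall_slice] <- hu_wall
    sl[lumen_slice] <- hu_lumen
    vol[z, , ] <- sl
  }
  # cap the tube ends with wall
  for (z in c(z0 - 1L, z0 - 2L, z1 + 1L, z1 + 2L)) {
    sl <- vol[z, , ]
    sl[wall_slice] <- hu_wall
    vol[z, , ] <- sl
  }
  list(volume = volume_image(vol, spacing = rep(spacing, 3)),
       axis_yx = c(cy, cy), z_range = c(z0, z1), radius_mm = radius_mm)
}
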