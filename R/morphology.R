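# 3D binary morphology on the voxel lattice: flood fill, component
# labelling, small-component removal and hole filling. 6-connectivity
# throughout. Implemented with vectorised frontier expansion over linear
# indices; per-iteration cost is O(frontier), iterations ~ grid diameter.

neighbours6 <- function(idx, dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  nxy <- nx * ny
  i0 <- idx - 1L  # 0-based
  x <- i0 %% nx
  y <- (i0 %/% nx) %% ny
  z <- i0 %/% nxy
  out <- c(
    idx[x > 0L] - 1L, idx[x < nx - 1L] + 1L,
    idx[y > 0L] - nx, idx[y < ny - 1L] + nx,
    idx[z > 0L] - nxy, idx[z < nz - 1L] + nxy
  )
  out
}

# all voxels of `candidate` (logical array) connected to seed indices
flood_fill <- function(candidate, seeds) {
  dims <- dim(candidate)
  visited <- logical(length(candidate))
  seeds <- seeds[candidate[seeds]]
  visited[seeds] <- TRUE
  frontier <- seeds
  while (length(frontier)) {
    nb <- unique(neighbours6(frontier, dims))
    nb <- nb[candidate[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  array(visited, dim = dims)
}

# label connected components; returns integer array (0 = background)
label_components <- function(mask) {
  dims <- dim(mask)
  labels <- integer(length(mask))
  remaining <- which(mask)
  lab <- 0L
  while (length(remaining)) {
    lab <- lab + 1L
    comp <- flood_fill(mask, remaining[1L])
    labels[comp] <- lab
    remaining <- remaining[!comp[remaining]]
  }
  array(labels, dim = dims)
}

# drop components whose physical volume is below min_cm3
remove_small_components <- function(mask, spacing_mm, min_cm3) {
  if (min_cm3 <= 0 || !any(mask)) return(mask)
  vox_cm3 <- prod(spacing_mm) / 1000
  labels <- label_components(mask)
  counts <- tabulate(labels[labels > 0L])
  keep <- which(counts * vox_cm3 >= min_cm3)
  array(labels %in% keep, dim = dim(mask))
}

# fill interior holes: background components not touching the array border
fill_holes <- function(mask) {
  dims <- dim(mask)
  bg <- !mask
  border <- border_indices(dims)
  outside <- flood_fill(bg, border[bg[border]])
  mask | (bg & !outside)
}

border_indices <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  idx <- array(seq_len(nx * ny * nz), dim = dims)
  unique(c(idx[c(1, nx), , ], idx[, c(1, ny), ], idx[, , c(1, nz)]))
}
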