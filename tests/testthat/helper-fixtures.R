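# Shared fixtures and independent brute-force oracles.

small_cylinder <- function(spacing = 1, depth = 6.5) {
  build_cylinder_phantom(diameter = 16, length = 25, spacing = spacing,
                         tumor = tumor_spec(3, 5, depth))
}

# a tiny two-material slab phantom for dose-engine oracles
tiny_slab_phantom <- function(dims = c(10, 10, 10), spacing = 0.8,
                              air_front_layers = 2) {
  mat <- array(1L, dims)
  if (air_front_layers > 0) mat[, seq_len(air_front_layers), ] <- 0L
  mat[1, , ] <- 0L    # one air column so rays can miss tissue
  mt <- data.frame(label = c(0L, 1L), name = c("air", "tissue"),
                   density = c(0.0012, 1.04))
  voxel_phantom(mat, rep(spacing, 3),
                c(-dims[1] / 2 * spacing, 0, -dims[3] / 2 * spacing), mt)
}

# independent per-voxel ray march re-deriving depth, radius and gap
oracle_dose_components <- function(phantom, beam, params) {
  dims <- dim(phantom$material_grid)
  sp <- phantom$spacing
  air <- 0L
  out <- lapply(c("thermal", "fast", "photon", "boron"),
                function(ch) array(0, dims))
  names(out) <- c("thermal", "fast", "photon", "boron")
  for (i in seq_len(dims[1])) for (k in seq_len(dims[3])) {
    entry <- NA
    tissue_len <- 0
    for (j in seq_len(dims[2])) {
      lab <- phantom$material_grid[i, j, k]
      yc <- phantom$origin[2] + (j - 0.5) * sp[2]
      if (lab == air) next
      if (is.na(entry)) entry <- phantom$origin[2] + (j - 1) * sp[2]
      d <- tissue_len + sp[2] / 2
      tissue_len <- tissue_len + sp[2]
      gap <- max(entry, 0)
      xc <- phantom$origin[1] + (i - 0.5) * sp[1]
      zc <- phantom$origin[3] + (k - 0.5) * sp[3]
      r <- sqrt((xc - beam$beam_axis_position[1])^2 +
                (zc - beam$beam_axis_position[2])^2)
      mod <- air_gap_attenuation(gap, beam, params) *
        off_axis_profile(r, d, gap, beam, params) *
        beam$reactor_power / 1.2
      for (ch in names(out))
        out[[ch]][i, j, k] <- depth_curve(ch, d, params) * mod
    }
  }
  out
}

# sort-based coverage-dose oracle: largest dose d with #(values >= d) at
# least q% of the voxels, i.e. the ceiling(n*q/100)-th largest value
oracle_d_percent <- function(values, q) {
  sv <- sort(values, decreasing = TRUE)
  n <- length(sv)
  sv[min(n, max(1L, ceiling(n * q / 100)))]
}

expect_rel_equal <- function(actual, expected, tol = 1e-9) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-300), tol)
}
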