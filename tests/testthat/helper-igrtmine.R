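# Small fixtures shared across tests; everything is generated in code.

# Compact lattice for fast geometric tests.
tiny_config <- function(n_patients = 8L, ...) {
  sim_config(n_patients = n_patients, grid_shape = c(16L, 16L, 12L),
             spacing = c(4, 4, 4), ...)
}

# A smooth positive random field with a reproducible seed.
random_dose <- function(dim = c(10L, 9L, 8L), spacing = c(4, 4, 4), seed = 1) {
  vals <- with_seed(seed, array(runif(prod(dim), 0, 60), dim))
  g <- dose_grid(vals, spacing)
  blur_map(g, sigma_mm = spacing)  # smooth so interpolation is well-behaved
}

# Linear field D(x) = slope * x (Gy, x in mm), padded non-negative.
linear_field_x <- function(dim = c(12L, 8L, 6L), spacing = c(2, 2, 2),
                           slope = 2) {
  g <- dose_grid(array(0, dim), spacing)
  xs <- grid_axis_coords(g, 1)
  vals <- array(rep(slope * (xs - min(xs)), times = dim[2] * dim[3]), dim)
  dose_grid(vals, spacing, g$origin)
}

# Brute-force integer-voxel index-shift oracle: out[i] = v[i + k], zero fill.
index_shift_oracle <- function(values, k) {
  dm <- dim(values)
  out <- array(0, dm)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (l in seq_len(dm[3])) {
    s <- c(i, j, l) + k
    if (all(s >= 1L) && all(s <= dm))
      out[i, j, l] <- values[s[1], s[2], s[3]]
  }
  out
}

# Construct a minimal tstat_map by hand (for region-extraction tests).
fake_tstat_map <- function(t_arr, spacing = c(4, 4, 4)) {
  mx <- max(t_arr, na.rm = TRUE)
  structure(list(t = t_arr, diff = t_arr, perm_sd = t_arr * 0 + 1,
                 max_t = mx,
                 argmax = which(t_arr == mx)[1],
                 global_p = NA_real_, n_perm = 0L, n_dead = 0L, n_alive = 0L,
                 perms = NULL, seed = NULL, dim = dim(t_arr),
                 spacing = spacing, origin = -(dim(t_arr) - 1) / 2 * spacing),
            class = "tstat_map")
}
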