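# Shared fixtures and independent brute-force oracles for the test suite.
# Oracles deliberately use naive per-cell loops, not the package's
# vectorised code paths.

toy_grid <- function(n = 50, cell_um = 1000) build_grid(n, n, cell_um)

# Naive per-cell distance (mm) from the grid centre.
brute_distance <- function(grid) {
  out <- matrix(NA_real_, grid$n_y, grid$n_x)
  cs <- grid$cell_size_um / 1000
  cx <- (grid$n_x + 1) / 2
  cy <- (grid$n_y + 1) / 2
  for (i in seq_len(grid$n_y)) {
    for (j in seq_len(grid$n_x)) {
      dx <- (j - cx) * cs
      dy <- (i - cy) * cs
      out[i, j] <- sqrt(dx^2 + dy^2)
    }
  }
  out
}

# Naive per-cell beam/penumbra/out classification counts.
brute_region_counts <- function(grid, beam_mm, pen_mm) {
  r <- brute_distance(grid)
  counts <- c(beam = 0L, penumbra = 0L, out = 0L)
  for (v in r) {
    if (v <= beam_mm) counts["beam"] <- counts["beam"] + 1L
    else if (v <= beam_mm + pen_mm) counts["penumbra"] <- counts["penumbra"] + 1L
    else counts["out"] <- counts["out"] + 1L
  }
  counts
}

# Naive masked sum by double loop.
brute_masked_sum <- function(mat, mask) {
  total <- 0
  for (i in seq_len(nrow(mat)))
    for (j in seq_len(ncol(mat)))
      if (mask[i, j]) total <- total + mat[i, j]
  total
}

# Reduced-resolution scenario config used by end-to-end tests: same 9 cm
# slice at 600 um cells.
quick_config <- function(modality = "bnct", mep_model = "circular",
                         ctv_margin_cm = 2.0, master_seed = 7, ...) {
  scenario_config(modality, mep_model, ctv_margin_cm,
                  master_seed = master_seed,
                  grid = list(n_x = 150L, n_y = 150L, cell_size_um = 600),
                  ...)
}

# Homogeneous radiosensitivity field (alpha, beta constant) on a grid.
homogeneous_rs <- function(grid, alpha, beta) {
  sample_radiosensitivity(grid, alpha_mean = alpha, alpha_sd = 0,
                          beta_mean = beta, beta_sd = 0, seed = 1)
}
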