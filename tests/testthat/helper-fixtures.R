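# Shared fixtures and independent oracles, built in code at test time.

printed_params <- function() {
  growth_params(C = 2.402, r = 0.235, a = 5.64, b = 4.00, c = 0.677, d = 0)
}

# A reduced consecutive-concentration design for fast fitting tests.
small_design <- function() {
  experiment_design(peg_levels = 1:12, excluded_levels = c(6),
                    das_range = c(7, 14), replications = 1)
}

noiseless_table <- function(design = experiment_design(),
                            params = printed_params(), seed = 1L) {
  generate_observations(design, params, noise_model(additive_sd = 0,
                                                    seed = seed))
}

# Grid-search oracle for the dose-response argmax (independent of
# optimal_peg's closed form).
grid_argmax_K <- function(params, lo = 0, hi = 30, step = 0.001) {
  grid <- seq(lo, hi, by = step)
  grid[which.max(full_length_K(grid, params))]
}

# Central-difference oracle for dK/dPEG.
fd_dK <- function(peg, params, h = 1e-6) {
  (full_length_K(peg + h, params) - full_length_K(peg - h, params)) / (2 * h)
}

# Skeleton-drawing helpers for image tests: masks built pixel by pixel.
vertical_line_mask <- function(n_px = 100, h = n_px + 20, w = 40,
                               mm_per_pixel = 0.5) {
  g <- matrix(FALSE, h, w)
  g[10 + seq_len(n_px), floor(w / 2)] <- TRUE
  root_mask(g, mm_per_pixel)
}

diagonal_line_mask <- function(n_px = 100, mm_per_pixel = 1) {
  g <- matrix(FALSE, n_px + 20, n_px + 20)
  for (i in seq_len(n_px)) g[10 + i, 10 + i] <- TRUE
  root_mask(g, mm_per_pixel)
}
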