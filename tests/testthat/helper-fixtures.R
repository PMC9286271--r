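# Small generators reused across test files.

well_separated_snapshot <- function(n = 10000, f = 0.05, seed = 1) {
  simulate_snapshot(snapshot_params(
    n_cells = n, sub_fraction = f, seed = seed))
}

# A tiny hand-built trace table: one cell, optional noiseless ramp.
ramp_trace <- function(onset_h = 24, slope_per_frame = 3, n_frames = 96,
                       dt_h = 0.5, baseline = 100, noise_sd = 0, seed = 1) {
  set.seed(seed)
  t <- (seq_len(n_frames) - 1) * dt_h
  v <- rep(baseline, n_frames)
  up <- t >= onset_h
  v[up] <- baseline + (t[up] - onset_h) / dt_h * slope_per_frame
  v + rnorm(n_frames, 0, noise_sd)
}

# Brute-force median-of-ratios oracle: explicit loops, no shared code with
# the implementation.
brute_force_size_factors <- function(counts) {
  n_genes <- nrow(counts); n_samples <- ncol(counts)
  geo <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    prod <- 1
    for (s in seq_len(n_samples)) prod <- prod * counts[g, s]
    geo[g] <- prod^(1 / n_samples)
  }
  sf <- numeric(n_samples)
  for (s in seq_len(n_samples)) {
    ratios <- c()
    for (g in seq_len(n_genes)) {
      if (geo[g] > 0) ratios <- c(ratios, counts[g, s] / geo[g])
    }
    sf[s] <- median(ratios)
  }
  sf
}

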