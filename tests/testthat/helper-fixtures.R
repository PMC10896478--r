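# Shared fixtures: tiny grids, toy series and independent dense oracles.
# The oracles deliberately use a different computational route than the
# package (full correlation/distance matrices via cor()/dist(), explicit
# loops) so that agreement is evidence, not tautology.

tiny_grid <- function(shape = c(5, 5, 4), semi = c(2.6, 2.6, 2.2), voxel = 3) {
  make_mask(simulation_config(grid_shape = shape, voxel_size_mm = voxel,
                              mask_semi_axes = semi))
}

random_series <- function(grid, nt = 60, seed = 1) {
  set.seed(seed)
  bold_series(matrix(rnorm(grid$n_voxels * nt), grid$n_voxels, nt), 2)
}

# dense brute-force FCS oracle (full N x N correlation matrix)
dense_fcs_oracle <- function(series, grid, r0 = 0.2) {
  R <- cor(t(series$data))
  R[is.na(R)] <- 0
  Z <- atanh(pmin(R, 1 - 1e-7))
  W <- Z * (R > r0)
  diag(W) <- 0
  rowSums(W) / (grid$n_voxels - 1)
}

# dense distance-binned oracle (full N x N distance matrix)
dense_binned_oracle <- function(series, grid, params) {
  R <- cor(t(series$data))
  R[is.na(R)] <- 0
  Z <- atanh(pmin(R, 1 - 1e-7))
  W <- Z * (R > params$r0)
  diag(W) <- 0
  D <- as.matrix(dist(grid$coords_mm))
  e <- params$bin_edges_mm
  vals <- sapply(seq_len(params$n_bins), function(k) {
    inbin <- D >= e[k] & (if (k == params$n_bins) D <= e[k + 1] else D < e[k + 1])
    rowSums(W * inbin) / (grid$n_voxels - 1)
  })
  unname(vals)
}

# elongated cohort whose mask spans > 170 mm so long-range bins are populated;
# four hubs at x = 12, 45, 135, 168 mm: every hub has a partner beyond 100 mm
long_range_config <- function(seed, n_patients = 10, n_controls = 10,
                              long_range_attenuation = 0.5, hub_coupling = 0.6,
                              noise_sd = 1, coupling_gain_sd = 0.15,
                              cognition_effect = 1, cognition_noise_sd = 0.3,
                              n_timepoints = 130) {
  simulation_config(
    grid_shape = c(60, 10, 8), mask_semi_axes = c(29, 4.2, 3.4),
    hub_centers = cbind(c(5, 16, 46, 57), 5, 4), hub_radius_mm = 6,
    n_patients = n_patients, n_controls = n_controls,
    n_timepoints = n_timepoints, hub_coupling = hub_coupling,
    long_range_attenuation = long_range_attenuation, noise_sd = noise_sd,
    coupling_gain_sd = coupling_gain_sd, cognition_effect = cognition_effect,
    cognition_noise_sd = cognition_noise_sd, seed = seed)
}

# smoothed long-range / per-bin FCS maps for one cohort
cohort_binned_maps <- function(cohort, params = connectivity_params(),
                               smooth_fwhm = 6) {
  g <- cohort$grid
  n <- nrow(cohort$table)
  fb <- array(0, c(n, g$n_voxels, params$n_bins))
  bm <- NULL
  for (i in seq_len(n)) {
    pp <- preprocess_bold(cohort$bold[[i]])
    b <- compute_binned_fcs(pp, g, params)
    fb[i, , ] <- b$values
    if (is.null(bm)) bm <- b$bin_masks
  }
  for (k in seq_len(params$n_bins)) fb[, , k] <- smooth_map(fb[, , k], g, smooth_fwhm)
  list(bins = fb, bin_masks = bm)
}

# amplitude gain of the band-pass filter at one frequency, measured by
# projecting the filtered sinusoid onto sin/cos over interior samples
measured_gain <- function(freq, tr = 2, nt = 512) {
  tt <- seq(0, by = tr, length.out = nt)
  x <- sin(2 * pi * freq * tt)
  y <- bandpass_filter(bold_series(matrix(x, 1), tr))$data[1, ]
  interior <- 100:412
  A <- cbind(sin(2 * pi * freq * tt[interior]), cos(2 * pi * freq * tt[interior]))
  sqrt(sum(qr.solve(A, y[interior])^2))
}

ancova_design_df <- function(tab) {
  data.frame(group = as.integer(tab$group == "patient"), age = tab$age,
             sex = tab$sex, education = tab$education)
}
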