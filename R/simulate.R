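#' Synthetic cohort simulation configuration
#'
#' Defines a two-group (patient / control) cohort of masked 4D BOLD-like
#' series with known ground truth: spatially localized hubs emitting
#' band-limited latent signals, inter-hub coupling that decays with the
#' subject-independent latent correlation matrix, a patient-specific
#' multiplicative attenuation of couplings between hubs separated by more
#' than `long_range_cut_mm`, per-subject connectivity gains, and a cognitive
#' domain score generated from each subject's hub-connectivity summary.
#'
#' @param grid_shape 3 positive integers (voxels per axis).
#' @param voxel_size_mm voxel size in mm (default 3, isotropic).
#' @param n_timepoints timepoints per subject (default 240, i.e. 8 min at
#'   TR 2 s, including the volumes later discarded).
#' @param repetition_time_s repetition time in seconds (default 2).
#' @param n_patients,n_controls group sizes (defaults 32 and 34).
#' @param hub_centers matrix/list of 1-based voxel indices (rows = hubs);
#'   must all lie inside the mask. `NULL` places 3 hubs along the longest
#'   mask axis.
#' @param hub_radius_mm radius defining the ground-truth hub mask (default 9).
#' @param coupling_decay_mm Gaussian sigma (mm) of the spatial hub loading;
#'   loadings below 0.01 are truncated to zero for sparsity (default 6).
#' @param hub_coupling baseline latent correlation between distinct hubs
#'   (default 0.6).
#' @param long_range_attenuation patient multiplier, in `[0, 1]`, applied to
#'   latent couplings of hub pairs farther apart than `long_range_cut_mm`;
#'   1 means no group effect (default 0.5).
#' @param long_range_cut_mm distance cut for the patient attenuation
#'   (default 100).
#' @param noise_sd SD of white observation noise per voxel (default 1).
#' @param smooth_noise_fwhm_mm FWHM of the spatially smooth noise component,
#'   0 disables it (default 6).
#' @param smooth_noise_sd marginal SD of the smooth noise component
#'   (default `noise_sd / 2`).
#' @param coupling_gain_sd SD of the per-subject multiplicative gain on all
#'   inter-hub couplings (default 0.15; gains are clipped to `[0.2, 1.6]`).
#'   This is the across-subject variation that the brain-behaviour analysis
#'   recovers.
#' @param cognition_effect slope linking a subject's mean inter-hub coupling
#'   to the information-processing-speed score (default 1).
#' @param cognition_noise_sd SD of the independent noise on that score
#'   (default 0.3).
#' @param mask_semi_axes,mask_center optional ellipsoid parameters passed to
#'   [make_mask()] (voxel units).
#' @param seed cohort seed (integer).
#' @return Object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(grid_shape = c(20L, 24L, 20L), voxel_size_mm = 3,
                              n_timepoints = 240L, repetition_time_s = 2,
                              n_patients = 32L, n_controls = 34L,
                              hub_centers = NULL, hub_radius_mm = 9,
                              coupling_decay_mm = 6, hub_coupling = 0.6,
                              long_range_attenuation = 0.5,
                              long_range_cut_mm = 100,
                              noise_sd = 1, smooth_noise_fwhm_mm = 6,
                              smooth_noise_sd = noise_sd / 2,
                              coupling_gain_sd = 0.15,
                              cognition_effect = 1, cognition_noise_sd = 0.3,
                              mask_semi_axes = NULL, mask_center = NULL,
                              seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
              n_timepoints = as.integer(n_timepoints),
              repetition_time_s = repetition_time_s,
              n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
              hub_centers = hub_centers, hub_radius_mm = hub_radius_mm,
              coupling_decay_mm = coupling_decay_mm, hub_coupling = hub_coupling,
              long_range_attenuation = long_range_attenuation,
              long_range_cut_mm = long_range_cut_mm,
              noise_sd = noise_sd, smooth_noise_fwhm_mm = smooth_noise_fwhm_mm,
              smooth_noise_sd = smooth_noise_sd,
              coupling_gain_sd = coupling_gain_sd,
              cognition_effect = cognition_effect,
              cognition_noise_sd = cognition_noise_sd,
              mask_semi_axes = mask_semi_axes, mask_center = mask_center,
              seed = as.integer(seed))
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 1L))
    stop("grid_shape must be 3 positive integers")
  if (cfg$voxel_size_mm <= 0) stop("voxel_size_mm must be positive")
  if (cfg$n_timepoints < 2L) stop("n_timepoints must be >= 2")
  if (cfg$long_range_attenuation < 0 || cfg$long_range_attenuation > 1)
    stop("long_range_attenuation must lie in [0, 1]")
  if (cfg$hub_coupling < 0 || cfg$hub_coupling >= 1)
    stop("hub_coupling must lie in [0, 1)")
  if (cfg$noise_sd < 0 || cfg$smooth_noise_fwhm_mm < 0)
    stop("noise_sd and smooth_noise_fwhm_mm must be nonnegative")
  class(cfg) <- "simulation_config"
  cfg
}

## deterministic per-subject seed from (cohort seed, subject index); < 2^31
subject_seed <- function(cohort_seed, index) {
  (as.double(cohort_seed) * 10007 + 7919 * as.double(index)) %% 2147483629
}

hub_centers_matrix <- function(config, grid) {
  hc <- config$hub_centers
  if (is.null(hc)) {
    ax <- which.max(grid$dim)
    ctr <- round((grid$dim + 1) / 2)
    pos <- round(seq(0.2, 0.8, length.out = 3L) * (grid$dim[ax] - 1)) + 1L
    hc <- matrix(rep(ctr, each = 3L), nrow = 3L)
    hc[, ax] <- pos
  }
  if (is.list(hc)) hc <- do.call(rbind, hc)
  hc <- matrix(as.integer(hc), ncol = 3L)
  inside <- grid$mask[hc]
  if (!all(inside))
    stop("hub_centers outside the mask: rows ", paste(which(!inside), collapse = ", "))
  hc
}

## latent inter-hub correlation matrix for one group (before subject gain)
latent_coupling <- function(config, grid, hc, group) {
  m <- nrow(hc)
  cmm <- sweep(hc - 1, 2L, grid$voxel_size_mm, `*`)
  Dh <- as.matrix(stats::dist(cmm))
  C <- matrix(config$hub_coupling, m, m)
  diag(C) <- 1
  if (identical(group, "patient")) {
    far <- Dh > config$long_range_cut_mm
    C[far] <- C[far] * config$long_range_attenuation
  }
  list(C = C, hub_distances_mm = Dh)
}

## repair to the nearest correlation matrix when attenuation/gain break PD
repair_correlation <- function(C) {
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) > 1e-8) return(list(C = C, repaired = FALSE))
  Cr <- as.matrix(Matrix::nearPD(C, corr = TRUE)$mat)
  list(C = unname(Cr), repaired = TRUE)
}

## band-limited latent signals (rows) whose empirical correlation matrix is
## exactly C: band-passed white noise is mean-centred, orthonormalized (any
## linear combination of centred rows stays centred and band-limited), then
## mixed through the Cholesky factor of C
latent_signals <- function(C, n_timepoints, repetition_time_s) {
  m <- nrow(C)
  bf <- bandpass_design(0.01, 0.1, repetition_time_s)
  E <- matrix(stats::rnorm(m * n_timepoints), m, n_timepoints)
  E <- t(filtfilt_cols(t(E), bf$b, bf$a))
  E <- E - rowMeans(E)
  Q <- qr.Q(qr(t(E)))                       # T x m orthonormal, columns centred
  t(chol(C)) %*% (t(Q) * sqrt(n_timepoints - 1))
}

#' Simulate one subject's masked BOLD series
#'
#' Each hub emits a band-limited (0.01-0.1 Hz) latent signal; the latent
#' signals of group g are correlated according to that group's latent
#' coupling matrix (patients attenuate couplings of hub pairs beyond
#' `long_range_cut_mm` by `long_range_attenuation`), scaled by a per-subject
#' connectivity gain derived deterministically from `subject_seed`. A voxel's
#' time course is the loading-weighted sum of hub signals (Gaussian spatial
#' loading, sigma `coupling_decay_mm`, truncated below 0.01) plus spatially
#' smooth noise plus white noise. Non-positive-definite requested coupling
#' matrices are repaired to the nearest correlation matrix and flagged.
#'
#' @param config a [simulation_config()].
#' @param group `"patient"` or `"control"`.
#' @param subj_seed integer seed for this subject (see the deterministic
#'   derivation used by [simulate_cohort()]).
#' @param grid optional pre-built [make_mask()] grid (rebuilt if `NULL`).
#' @return List with `series` (a [bold_series()]) and `ground_truth`: hub
#'   mask (logical per in-mask voxel), hub centres, group coupling matrix,
#'   subject coupling matrix (after gain), subject gain, hub-connectivity
#'   summary (mean off-diagonal subject coupling), repair flag.
#' @export
simulate_subject_bold <- function(config, group = c("patient", "control"),
                                  subj_seed, grid = NULL) {
  group <- match.arg(group)
  if (is.null(grid)) grid <- make_mask(config)
  if (!isTRUE(attr(grid, "fcs_valid"))) stop("mask has fewer than 2 voxels")
  if (config$n_timepoints < 50L) stop("n_timepoints must be >= 50 for simulation")
  hc <- hub_centers_matrix(config, grid)
  lat <- latent_coupling(config, grid, hc, group)

  set.seed(as.integer(subj_seed %% 2147483629))
  gain <- 1
  if (config$coupling_gain_sd > 0)
    gain <- min(max(stats::rnorm(1, 1, config$coupling_gain_sd), 0.2), 1.6)
  Cs <- lat$C
  off <- row(Cs) != col(Cs)
  Cs[off] <- Cs[off] * gain
  rep_ <- repair_correlation(Cs)

  S <- latent_signals(rep_$C, config$n_timepoints, config$repetition_time_s)

  ## spatial loadings: in-mask voxels x hubs
  hub_cmm <- sweep(hc - 1, 2L, grid$voxel_size_mm, `*`)
  d2 <- outer(rowSums(grid$coords_mm^2), rowSums(hub_cmm^2), `+`) -
    2 * tcrossprod(grid$coords_mm, hub_cmm)
  L <- exp(-pmax(d2, 0) / (2 * config$coupling_decay_mm^2))
  L[L < 0.01] <- 0

  Y <- L %*% S
  if (config$smooth_noise_fwhm_mm > 0 && config$smooth_noise_sd > 0) {
    for (tt in seq_len(ncol(Y)))
      Y[, tt] <- Y[, tt] + config$smooth_noise_sd *
        smoothed_null_field(grid, config$smooth_noise_fwhm_mm)
  }
  if (config$noise_sd > 0)
    Y <- Y + config$noise_sd * matrix(stats::rnorm(length(Y)), nrow(Y))

  dmin2 <- apply(d2, 1L, min)
  gt <- list(hub_mask = dmin2 <= config$hub_radius_mm^2,
             hub_centers = hc, hub_distances_mm = lat$hub_distances_mm,
             group_coupling = lat$C, subject_coupling = rep_$C,
             gain = gain,
             hub_summary = if (nrow(hc) > 1) mean(rep_$C[off]) else 1,
             coupling_repaired = rep_$repaired)
  list(series = bold_series(Y, config$repetition_time_s, mask_ref = "sim"),
       ground_truth = gt)
}

## per-subject deterministic latent draws shared by the BOLD generator and
## the cohort table (gain + demographics use disjoint RNG streams)
cohort_subjects <- function(config) {
  n <- config$n_patients + config$n_controls
  data.frame(
    subject = sprintf("sub%03d", seq_len(n)),
    group = rep(c("patient", "control"), c(config$n_patients, config$n_controls)),
    seed = subject_seed(config$seed, seq_len(n)),
    stringsAsFactors = FALSE)
}

#' Simulate the cohort subject table
#'
#' Demographics are drawn from group-specific distributions whose defaults
#' match a moderate-to-severe white-matter-hyperintensity cohort versus
#' healthy controls: age N(65.2, 10.1) / N(71.0, 8.0) years, education
#' N(11.0, 3.4) / N(12.3, 3.5) years, male probability 17/36 vs 7/34.
#' The information-processing-speed composite is generated as
#' `cognition_effect * (subject hub-connectivity summary, centred) + noise`,
#' so brain-behaviour recovery is testable against ground truth; the
#' remaining domain composites are drawn from group-specific normals
#' (patients below controls).
#'
#' @param config a [simulation_config()].
#' @return `data.frame` with subject, group, seed, gain, hub_summary, age,
#'   sex (1 = male), education, mmse, episodic_memory, executive_function,
#'   information_processing_speed, visuospatial_function.
#' @export
simulate_cohort_table <- function(config) {
  if (config$n_patients < 2L || config$n_controls < 2L)
    stop("need at least 2 subjects per group")
  subs <- cohort_subjects(config)
  grid <- make_mask(config)
  hc <- hub_centers_matrix(config, grid)

  ## per-subject gain + hub summary from the same seeds as the BOLD generator
  gain <- vapply(seq_len(nrow(subs)), function(i) {
    set.seed(as.integer(subs$seed[i] %% 2147483629))
    if (config$coupling_gain_sd > 0)
      min(max(stats::rnorm(1, 1, config$coupling_gain_sd), 0.2), 1.6) else 1
  }, numeric(1))
  summ <- vapply(seq_len(nrow(subs)), function(i) {
    C <- latent_coupling(config, grid, hc, subs$group[i])$C
    off <- row(C) != col(C)
    Cs <- C; Cs[off] <- Cs[off] * gain[i]
    Cs <- repair_correlation(Cs)$C
    if (nrow(C) > 1) mean(Cs[off]) else 1
  }, numeric(1))

  set.seed(as.integer((config$seed * 977 + 13) %% 2147483629))
  pat <- subs$group == "patient"
  n <- nrow(subs)
  age <- ifelse(pat, stats::rnorm(n, 65.2, 10.1), stats::rnorm(n, 71.0, 8.0))
  edu <- pmax(ifelse(pat, stats::rnorm(n, 11.0, 3.4), stats::rnorm(n, 12.3, 3.5)), 0)
  sex <- stats::rbinom(n, 1L, ifelse(pat, 17 / 36, 7 / 34))
  mmse <- pmin(round(ifelse(pat, stats::rnorm(n, 26.4, 3.7), stats::rnorm(n, 28.3, 1.6))), 30)
  dom <- function(mp, sp, mc, sc) ifelse(pat, stats::rnorm(n, mp, sp), stats::rnorm(n, mc, sc))
  ips <- config$cognition_effect * (summ - mean(summ)) +
    stats::rnorm(n, 0, config$cognition_noise_sd)
  data.frame(subs, gain = gain, hub_summary = summ,
             age = age, sex = sex, education = edu, mmse = mmse,
             episodic_memory = dom(-0.32, 0.74, 0.34, 0.63),
             executive_function = dom(-0.31, 0.70, 0.33, 0.56),
             information_processing_speed = ips,
             visuospatial_function = dom(-0.07, 1.09, 0.08, 0.56),
             stringsAsFactors = FALSE)
}

#' Simulate a full two-group cohort
#'
#' Builds the mask once, derives per-subject seeds deterministically from the
#' cohort seed, and generates each subject's BOLD series plus the shared
#' subject table. Subject-by-subject reproducible: subject i's data depends
#' only on (cohort seed, i).
#'
#' @param config a [simulation_config()].
#' @param keep_bold keep the per-subject series in memory (default TRUE).
#' @return List with `grid`, `table` (see [simulate_cohort_table()]),
#'   `bold` (list of [bold_series()] or NULL), `ground_truth` (first
#'   subject's hub geometry plus both group coupling matrices), `config`.
#' @export
simulate_cohort <- function(config, keep_bold = TRUE) {
  grid <- make_mask(config)
  tab <- simulate_cohort_table(config)
  bold <- vector("list", nrow(tab))
  gt <- NULL
  for (i in seq_len(nrow(tab))) {
    s <- simulate_subject_bold(config, tab$group[i], tab$seed[i], grid)
    if (is.null(gt)) {
      gt <- s$ground_truth
      gt$patient_coupling <- latent_coupling(config, grid,
                                             s$ground_truth$hub_centers, "patient")$C
      gt$control_coupling <- latent_coupling(config, grid,
                                             s$ground_truth$hub_centers, "control")$C
    }
    if (keep_bold) bold[[i]] <- s$series
  }
  list(grid = grid, table = tab, bold = if (keep_bold) bold else NULL,
       ground_truth = gt, config = config)
}
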