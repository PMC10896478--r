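#' Load and validate a pipeline configuration
#'
#' One YAML (or R list) configuration drives the full pipeline; defaults
#' mirror the standard analysis (discard 10 volumes, band 0.01-0.1 Hz,
#' r0 0.2, 18 x 10 mm bins, short/long cut 100 mm, 6 mm smoothing,
#' voxel-p 0.05, alpha 0.05, 1000 Monte Carlo iterations). Validation
#' happens before any computation.
#'
#' @param config path to a YAML file, or a named list with optional entries
#'   `simulation` (arguments of [simulation_config()]), `preprocess`
#'   (`n_discard`, `low_hz`, `high_hz`), `connectivity` (arguments of
#'   [connectivity_params()]), `stats` (`voxel_p`, `alpha`, `n_iterations`,
#'   `connectivity`, `smooth_fwhm_mm`, `mc_seed`).
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  sim <- do.call(simulation_config, config$simulation %||% list())
  pre <- utils::modifyList(list(n_discard = 10L, low_hz = 0.01, high_hz = 0.1),
                           config$preprocess %||% list())
  conn <- do.call(connectivity_params, config$connectivity %||% list())
  st <- utils::modifyList(list(voxel_p = 0.05, alpha = 0.05,
                               n_iterations = 1000L, connectivity = 26L,
                               smooth_fwhm_mm = 6, mc_seed = 7L),
                          config$stats %||% list())
  cc <- cluster_correction_params(st$voxel_p, st$alpha, st$n_iterations,
                                  st$connectivity)
  if (pre$n_discard < 0) stop("n_discard must be nonnegative")
  if (st$smooth_fwhm_mm < 0) stop("smooth_fwhm_mm must be nonnegative")
  structure(list(simulation = sim, preprocess = pre, connectivity = conn,
                 stats = st, cluster = cc), class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes simulate -> temporal preprocessing -> full-range and
#' distance-binned FCS -> short/long aggregation -> 6 mm map smoothing ->
#' voxel-wise ANCOVA with Monte Carlo cluster-extent correction (full range
#' and per distance bin, each corrected within its own bin mask) ->
#' voxel-wise brain-behaviour regression of the information-processing-speed
#' composite on short- and long-range FCS in the patient group -> report.
#'
#' @param config a [pipeline_config()] (or anything it accepts).
#' @param out_dir optional output directory; when given, writes the mask,
#'   hub ground truth and per-subject 4D series plus FCS maps as NIfTI, the
#'   subject table and cluster tables as TSV, per-bin significant-voxel
#'   counts as TSV, and a JSON run manifest declaring every output file.
#' @param verbose print stage progress.
#' @return List: `grid`, `table`, `summary` (cohort demographics table),
#'   `fcs` (subjects x voxels, smoothed), `binned_counts` (per-bin counts of
#'   cluster-surviving voxels, the distance profile of the group effect),
#'   `full_clusters`, `bin_clusters` (list), `behaviour` (short/long stat
#'   maps + clusters), `smoothness_fwhm_mm`, `extent` (full-mask Monte Carlo
#'   threshold), `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, verbose = TRUE) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  say <- function(...) if (verbose) message(...)
  manifest <- list(config = cfg[c("preprocess", "stats")],
                   simulation_seed = cfg$simulation$seed, outputs = character())

  say("stage 1/6: simulating cohort")
  cohort <- simulate_cohort(cfg$simulation)
  grid <- cohort$grid
  tab <- cohort$table
  n <- nrow(tab)

  say("stage 2/6: preprocessing + FCS (", n, " subjects)")
  conn <- cfg$connectivity
  nb <- conn$n_bins
  fcs_full <- matrix(0, n, grid$n_voxels)
  fcs_short <- matrix(0, n, grid$n_voxels)
  fcs_long <- matrix(0, n, grid$n_voxels)
  fcs_bins <- array(0, c(n, grid$n_voxels, nb))
  bin_masks <- NULL
  for (i in seq_len(n)) {
    pp <- preprocess_bold(cohort$bold[[i]], n_discard = cfg$preprocess$n_discard,
                          low_hz = cfg$preprocess$low_hz,
                          high_hz = cfg$preprocess$high_hz)
    bf <- compute_binned_fcs(pp, grid, conn)
    agg <- aggregate_range(bf)
    fcs_full[i, ] <- rowSums(bf$values)
    fcs_short[i, ] <- agg$short
    fcs_long[i, ] <- agg$long
    fcs_bins[i, , ] <- bf$values
    if (is.null(bin_masks)) bin_masks <- bf$bin_masks
  }

  say("stage 3/6: smoothing maps (", cfg$stats$smooth_fwhm_mm, " mm FWHM)")
  sm <- function(M) smooth_map(M, grid, cfg$stats$smooth_fwhm_mm)
  fcs_full <- sm(fcs_full); fcs_short <- sm(fcs_short); fcs_long <- sm(fcs_long)
  for (k in seq_len(nb)) fcs_bins[, , k] <- sm(fcs_bins[, , k])

  say("stage 4/6: group ANCOVA + Monte Carlo cluster correction")
  design <- data.frame(group = as.integer(tab$group == "patient"),
                       age = tab$age, sex = tab$sex, education = tab$education)
  full_stat <- voxelwise_ancova(fcs_full, design)
  fwhm_est <- estimate_smoothness(full_stat$residuals, grid)
  thr <- monte_carlo_cluster_threshold(grid, fwhm_est, cfg$cluster,
                                       seed = cfg$stats$mc_seed)
  full_clusters <- extract_clusters(full_stat, grid, thr$extent_voxels, cfg$cluster)

  bin_clusters <- vector("list", nb)
  binned_counts <- integer(nb)
  for (k in seq_len(nb)) {
    bm <- bin_masks[, k]
    if (sum(bm) < full_stat$n + 2L) { bin_clusters[[k]] <- extract_clusters(
      numeric(grid$n_voxels), grid, 0L, cfg$cluster, df = Inf); next }
    st_k <- voxelwise_ancova(fcs_bins[, , k], design)
    thr_k <- monte_carlo_cluster_threshold(grid, fwhm_est, cfg$cluster,
                                           seed = cfg$stats$mc_seed + k, mask = bm)
    cl_k <- extract_clusters(st_k, grid, thr_k$extent_voxels, cfg$cluster, mask = bm)
    bin_clusters[[k]] <- cl_k
    binned_counts[k] <- sum(cl_k$n_voxels)
  }

  say("stage 5/6: brain-behaviour regression (patients)")
  pat <- tab$group == "patient"
  bdesign <- data.frame(score = tab$information_processing_speed[pat],
                        age = tab$age[pat], sex = tab$sex[pat],
                        education = tab$education[pat])
  behaviour <- list(
    short = voxelwise_behaviour_regression(fcs_short[pat, , drop = FALSE], bdesign),
    long = voxelwise_behaviour_regression(fcs_long[pat, , drop = FALSE], bdesign))
  behaviour$long_clusters <- extract_clusters(behaviour$long, grid,
                                              thr$extent_voxels, cfg$cluster)
  behaviour$short_clusters <- extract_clusters(behaviour$short, grid,
                                               thr$extent_voxels, cfg$cluster)

  say("stage 6/6: report")
  summary_tab <- cohort_summary(tab)
  res <- list(grid = grid, table = tab, summary = summary_tab,
              fcs = fcs_full, binned_counts = binned_counts,
              bin_edges_mm = conn$bin_edges_mm,
              full_stat = full_stat, full_clusters = full_clusters,
              bin_clusters = bin_clusters, behaviour = behaviour,
              smoothness_fwhm_mm = fwhm_est, extent = thr,
              ground_truth = cohort$ground_truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(out_dir, ...)
    outs <- character()
    write_volume(grid$mask, p("mask.nii.gz"), grid$voxel_size_mm)
    outs <- c(outs, "mask.nii.gz")
    write_volume(map_to_array(as.numeric(cohort$ground_truth$hub_mask), grid),
                 p("hub_mask.nii.gz"), grid$voxel_size_mm)
    outs <- c(outs, "hub_mask.nii.gz")
    write_volume(map_to_array(t(fcs_full), grid), p("fcs_full_stack.nii.gz"),
                 grid$voxel_size_mm)
    outs <- c(outs, "fcs_full_stack.nii.gz")
    write_volume(map_to_array(full_stat$t, grid), p("group_tmap.nii.gz"),
                 grid$voxel_size_mm)
    outs <- c(outs, "group_tmap.nii.gz")
    ## per-bin maps as one 4D file (bin index on the 4th axis) + sidecar
    ## naming the bin edges
    bin_mean <- apply(fcs_bins, c(2, 3), mean)
    write_volume(map_to_array(bin_mean, grid), p("fcs_bins_mean.nii.gz"),
                 grid$voxel_size_mm)
    jsonlite::write_json(list(fourth_axis = "distance_bin",
                              bin_edges_mm = conn$bin_edges_mm),
                         p("fcs_bins_mean.json"), auto_unbox = TRUE, digits = NA)
    outs <- c(outs, "fcs_bins_mean.nii.gz", "fcs_bins_mean.json")
    utils::write.table(tab, p("subjects.tsv"), sep = "\t", row.names = FALSE,
                       quote = FALSE)
    utils::write.table(summary_tab, p("cohort_summary.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(full_clusters, p("full_clusters.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(bin = seq_len(nb), lower_mm = conn$bin_edges_mm[-(nb + 1)],
                 upper_mm = conn$bin_edges_mm[-1], n_significant = binned_counts),
      p("bin_significant_counts.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
    outs <- c(outs, "subjects.tsv", "cohort_summary.tsv", "full_clusters.tsv",
              "bin_significant_counts.tsv")
    manifest$outputs <- outs
    manifest$smoothness_fwhm_mm <- fwhm_est
    manifest$extent_voxels <- thr$extent_voxels
    manifest$mc_seed <- cfg$stats$mc_seed
    write_manifest(manifest, p("manifest.json"))
    res$manifest <- c(manifest, manifest_path = p("manifest.json"))
  } else {
    manifest$smoothness_fwhm_mm <- fwhm_est
    manifest$extent_voxels <- thr$extent_voxels
    res$manifest <- manifest
  }
  res
}
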