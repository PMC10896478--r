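# fcsconn — distance-resolved functional connectivity strength

`fcsconn` is an R package for voxel-wise weighted degree centrality
(*functional connectivity strength*, FCS) analysis of resting-state fMRI,
resolved by connection distance. It is aimed at researchers studying how
diffuse white-matter disease (e.g. white matter hyperintensities in cerebral
small vessel disease) disrupts brain network hubs, and specifically whether
that disruption concentrates in long-range connections.

## The statistic

For grey-matter voxel *i* out of *N* in-mask voxels,

    FCS(i) = 1/(N−1) · Σ_{j≠i, r_ij > r0} z_ij,      z_ij = atanh(r_ij)

where `r_ij` is the Pearson correlation between preprocessed voxel time
courses and `r0 = 0.2` discards weak, noise-prone edges; only positive
correlations contribute. The distance-resolved variant splits the same sum
into 18 half-open Euclidean-distance bins of 10 mm (0–180 mm):

    FCS(i,k) = 1/(N−1) · Σ_{j≠i, r_ij > r0, 10(k−1) ≤ D_ij < 10k} z_ij

with short-range (0–100 mm) and long-range (100–180 mm) aggregates. Because
every bin keeps the same 1/(N−1) normalisation, the bins sum exactly to the
full-range map — an invariant the test suite checks to 1e−9.

Around the statistic the package provides the full chain: temporal
preprocessing (volume discard, zero-phase 0.01–0.1 Hz band-pass, combined
detrend + nuisance regression), streamed FCS/binned-FCS computation (the
N×N correlation matrix is never materialised), 6 mm Gaussian map smoothing,
voxel-wise ANCOVA group comparison with Monte-Carlo-calibrated
cluster-extent correction confined to each analysis mask, voxel-wise
brain–behaviour regression, composite neuropsychological domain Z-scores,
NIfTI I/O, and a synthetic two-group cohort generator with planted hubs,
distance-dependent coupling, a patient-specific long-range attenuation and
a cognition score tied to hub connectivity — so every stage is validated
against known ground truth.

## Worked example

Simulate a small two-group cohort with two hubs 39 mm apart whose coupling
is halved in patients beyond a 30 mm cut, then run the full pipeline:

```r
library(fcsconn)

cfg <- list(
  simulation = list(grid_shape = c(24, 12, 10), mask_semi_axes = c(11, 5, 4.2),
                    hub_centers = rbind(c(6, 6, 5), c(19, 6, 5)), hub_radius_mm = 6,
                    n_patients = 8, n_controls = 8, n_timepoints = 120,
                    long_range_attenuation = 0.5, long_range_cut_mm = 30,
                    noise_sd = 0.8, seed = 11),
  connectivity = list(n_bins = 8L, distance_max_mm = 80, short_long_cut_mm = 40),
  stats = list(n_iterations = 300L, mc_seed = 3L))

res <- run_pipeline(cfg, verbose = FALSE)
res$summary
res$binned_counts
```

Output (abridged):

```
                      variable     patients     controls   test       p
1                          age 65.68 ± 9.98 74.65 ± 8.72      t 0.07624
3                    sex (M/F)          6/2          0/8   chi2 0.00195
7 information_processing_speed -0.26 ± 0.33  0.25 ± 0.38 ancova 0.01568

per-bin significant voxels: 0 0 0 245 339 103 0 0
estimated smoothness (mm):  8.5 8.82 9.26
extent threshold: 62 voxels = 1674 mm^3
```

Reading this: the cohort table reproduces the intended demographic structure
(patients younger, more often male, slower processing speed). The per-bin
counts are the distance profile of the group difference — cluster-surviving
voxels appear only in the 30–60 mm bins, straddling the planted 39 mm
inter-hub distance whose coupling was attenuated, while the full-range map
(`res$full_clusters`) shows no surviving cluster in this small cohort: the
distance-resolved analysis localises a disruption that the aggregate
statistic dilutes. `res$behaviour` holds the brain–behaviour t maps for the
patient group, and with `out_dir=` every map, table and a JSON run manifest
are written to disk.

Each stage is also callable on its own (`make_mask()`,
`simulate_cohort()`, `preprocess_bold()`, `compute_fcs()`,
`compute_binned_fcs()`, `aggregate_range()`, `smooth_map()`,
`voxelwise_ancova()`, `estimate_smoothness()`,
`monte_carlo_cluster_threshold()`, `extract_clusters()`,
`voxelwise_behaviour_regression()`, `composite_z()`, `cohort_summary()`).

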