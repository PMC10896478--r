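---
title: "Distance-resolved functional connectivity strength: models, parameters and validation"
author: "fcsconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-resolved functional connectivity strength: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Resting-state fMRI connectomics often summarises a voxel's role in the
whole-brain network by its *functional connectivity strength* (FCS) — the
weighted degree centrality of the voxel in the graph whose edges are
suprathreshold positive correlations between voxel time courses. In cerebral
small vessel disease, white matter hyperintensities are thought to damage
preferentially the long, metabolically expensive association fibres, so a
natural question is whether hub disruptions are *connection-distance
dependent*: do group differences concentrate in edges whose endpoints are far
apart? `fcsconn` implements the full analysis chain needed to ask this
question, together with a synthetic cohort generator that plants a known
answer, so that every stage can be validated end to end.

## The statistic

For in-mask voxel $i$ out of $N$ grey-matter voxels,

$$\mathrm{FCS}(i) \;=\; \frac{1}{N-1} \sum_{j \ne i,\; r_{ij} > r_0} z_{ij},
\qquad z_{ij} = \operatorname{atanh}(r_{ij}),$$

where $r_{ij}$ is the Pearson correlation between the preprocessed time
courses of voxels $i$ and $j$ and $r_0 = 0.2$ discards weak edges that are
plausibly noise. Only positive correlations contribute (after global-signal
regression the negative tail is hard to interpret), the inequality is strict,
and all FCS values are therefore nonnegative. The distance-resolved variant
splits the same sum by the Euclidean distance $D_{ij}$ between the voxels'
mm coordinates into 18 half-open bins of 10 mm covering 0–180 mm:

$$\mathrm{FCS}(i,k) \;=\; \frac{1}{N-1}
  \sum_{\substack{j \ne i,\; r_{ij} > r_0 \\ 10(k-1) \le D_{ij} < 10k}} z_{ij}.$$

Two properties follow directly from keeping the *same* $1/(N-1)$
normalisation in every bin (rather than a per-bin neighbour count) and are
used as machine-checked invariants throughout the test suite:
$\sum_k \mathrm{FCS}(i,k) = \mathrm{FCS}(i)$ exactly, and the short-range
(0–100 mm) plus long-range (100–180 mm) aggregates reconstruct the full map.

Numerical details worth stating:

* correlations are capped at $1 - 10^{-7}$ before the Fisher transform so
  perfectly correlated voxel pairs (possible in synthetic data) stay finite;
* zero-variance voxels get correlation 0 with everything (so they never pass
  $r_0$) and are reported in a `zero_variance` attribute rather than
  propagating `NaN`;
* a pair at exactly 180 mm would join the last bin; the masks used here have
  diameters strictly below `distance_max_mm`, so the case never arises, and
  the dialect is documented rather than silently chosen;
* the $N \times N$ correlation matrix is never materialised: correlations
  are streamed in voxel blocks, and the result is bit-identical for block
  sizes 1, 7, 64 and $N$ (a tested invariant). The distance-bin geometry of
  a grid is computed once and memoised on the grid object, since it is
  shared by every subject of a cohort.

## Temporal preprocessing

The chain is: discard the first 10 volumes, band-pass 0.01–0.1 Hz, then a
single least-squares projection that removes an intercept, a linear trend
and any supplied nuisance regressors (motion parameters, global, CSF and WM
signals). The band-pass is an order-2 Butterworth applied forward and
backward, which makes it zero-phase — a lagged filter would distort
correlations — with odd-reflection end padding. Measured on interior samples
of a 512-point series at TR 2 s, the gain is 0.994 at 0.05 Hz and 0.0022 at
0.2 Hz; edge samples carry residual transients, which is why the gain
contracts are asserted away from the ends. Folding detrending into the
nuisance projection makes the two steps one orthogonal projection, so the
operation is idempotent and residuals are exactly orthogonal to every
regressor — both are tested properties, and the executed order is recorded
in a `preproc_log` attribute.

## Group inference

Group comparison is a voxel-wise linear model
`FCS ~ intercept + group + age + sex + education`; the signed group t
(patient minus control) is reported, and the one-way ANCOVA F is its square.
Brain–behaviour maps use `FCS ~ intercept + score + age + sex + education`
within the patient group.

Cluster-extent correction follows the Monte Carlo (AlphaSim) convention:
white noise on the analysis mask is smoothed to the estimated per-axis
smoothness of the residual maps, standardised *voxel-wise* using the exact
standard deviation of the mask-weighted smoothing operator (so edge voxels
are not over-represented among suprathreshold voxels), thresholded two-sided
at `voxel_p`, and the $(1-\alpha)$ quantile of the maximum cluster size over
iterations becomes the extent threshold; observed clusters must be strictly
larger to survive. Positive and negative excursions are labelled separately
(signed clusters), 26-connectivity by default, configurable to 18 or 6.
Residual smoothness is estimated from the variance of first differences of
standardised residual maps: with a Gaussian autocorrelation
$\rho(\Delta) = \exp(-\Delta^2/4\sigma^2)$, the lag-1 autocorrelation
$\rho = 1 - \tfrac{1}{2}\mathrm{var}(\mathrm{diff})$ inverts to a per-axis
FWHM, clipped below at one voxel size (white noise reports the clip).

Each distance bin is analysed within its own *bin mask* — the voxels that
have at least one candidate neighbour in that bin — and corrected within
that mask, because peripheral bins cover far fewer voxels than central ones.

Two calibration facts shaped the defaults and the validation design. First,
the discrete quantile plus the strict size inequality make the procedure
err on the conservative side by at most one voxel of extent. Second, the
Gaussian null is only exact for maps with many degrees of freedom: a t-field
with few df is rougher than a Gaussian field of the same nominal smoothness,
and at df 19 we measured a family-wise rate of 0.033 instead of 0.050. At
the cohort sizes this package emulates (32 + 34 subjects, df 61) the
measured rate over 300 fresh null cohorts is 0.060, statistically compatible
with the nominal 0.05. The family-wise error test therefore runs at the full
cohort size on a reduced grid (about 3 300 mask voxels), not at a reduced
subject count.

## The synthetic cohort generator

No public dataset accompanies the analysis, so validation uses cohorts with
planted ground truth. The generative model is deliberately simple and is an
artifact design, not a claim found in the source study:

* an ellipsoidal mask inside a 3 mm isotropic grid stands in for the
  grey-matter mask;
* $m$ hubs at chosen voxel centres each emit a latent signal, band-limited
  to 0.01–0.1 Hz by the same filter used in preprocessing (so preprocessing
  is gain-neutral on signal); latent signals are mean-centred,
  orthonormalised and mixed through the Cholesky factor of the group's
  latent coupling matrix, which makes their *empirical* correlation matrix
  exactly the requested one;
* the coupling matrix has unit diagonal and `hub_coupling` (default 0.6)
  off-diagonal; in patients, entries for hub pairs farther apart than
  `long_range_cut_mm` (default 100 mm) are multiplied by
  `long_range_attenuation` in $[0,1]$ — 1 means a null cohort;
* every subject carries a connectivity gain $g_s$ (normal, SD
  `coupling_gain_sd`, clipped to $[0.2, 1.6]$) multiplying all inter-hub
  couplings; if attenuation or gain breaks positive definiteness the matrix
  is repaired to the nearest correlation matrix (`Matrix::nearPD`) and
  flagged;
* voxel time courses are Gaussian spatial loadings (SD `coupling_decay_mm`,
  truncated below 0.01) times hub signals, plus spatially smooth noise plus
  white noise;
* demographics are drawn per group to match a moderate-to-severe white
  matter hyperintensity cohort versus older controls (age 65.2 ± 10.1 vs
  71.0 ± 8.0 years; education 11.0 ± 3.4 vs 12.3 ± 3.5 years; male fraction
  17/36 vs 7/34); the information-processing-speed composite is
  `cognition_effect` times the subject's mean inter-hub coupling (centred)
  plus independent noise, so brain–behaviour recovery has a known answer;
  the other domain composites are group-shifted normals.

The per-subject gain deserves a remark: without it, between-subject FCS
variation would be pure sampling noise and no brain–behaviour association
could exist in the generating model. It is the one mechanism in the
generator that creates *individual differences* in connectivity, and the
cognition score is tied to it through the subject's realised coupling
matrix.

Per-subject seeds derive deterministically from the cohort seed and subject
index, so cohorts are reproducible subject by subject. What the generator
does **not** emulate: head motion, scanner drift, physiological noise
spectra, spatial normalisation error, parcellation effects, or realistic
anatomy. Passing the recovery tests therefore shows the *pipeline* is
correct and calibrated under its stated model, not that any particular
clinical finding would replicate.

## Validation study designs and problem sizes

The test suite and `scripts/acceptance.R` run these studies (sizes chosen
as the package's validation design):

* **Oracle fidelity** — streamed full-range and binned FCS versus dense
  brute-force matrices on ~50-voxel masks, five seeds, agreement to
  $10^{-10}$; bin-sum conservation to $10^{-9}$ relative.
* **Family-wise error** — grid 24×24×20 (≈3 300 mask voxels), 6 mm
  smoothness, 1 000 Monte Carlo iterations, one derived threshold applied to
  200 fresh null cohorts of 32 + 34 subjects; the rejection rate must fall
  inside the binomial 95% interval around 0.05.
* **Distance-dependence recovery** — ten cohorts of 10 + 10 subjects on an
  elongated 60×10×8 mask (diameter ≈174 mm) with four hubs at 12, 45, 135
  and 168 mm along the long axis, so every hub has a partner beyond 100 mm;
  couplings beyond 100 mm attenuated by 0.5 in patients. In at least 9/10
  cohorts the per-bin count of cluster-surviving voxels must peak in a bin
  at or above 100 mm, and the patients' long-range hub FCS must be below
  the controls'.
* **Brain–behaviour recovery** — ten cohorts of 20 patients with
  `hub_coupling` 0.7, no group attenuation, `coupling_gain_sd` 0.25,
  `cognition_effect` 4 and score noise 0.2: at least 80% of planted hub
  voxels must show suprathreshold positive t for the score in the long-range
  FCS regression, while permuted scores must yield a suprathreshold fraction
  near `voxel_p` (averaged over 30 permutations).
* **Filter contracts, chi-square, composites** — closed-form and hand-oracle
  checks at trivial sizes.

On one CPU the full test suite runs in roughly ten minutes; the acceptance
script in about six.

## Parameter reference

| Parameter | Default | Meaning |
|---|---|---|
| `r0` | 0.2 | correlation threshold; strict, positive-only |
| `bin_width_mm`, `n_bins` | 10, 18 | distance binning, 0–180 mm |
| `short_long_cut_mm` | 100 | short/long aggregate boundary (a bin edge) |
| `n_discard` | 10 | initial volumes dropped |
| band | 0.01–0.1 Hz | zero-phase Butterworth order 2, forward–backward |
| smoothing FWHM | 6 mm | applied to FCS maps only, never to time series |
| `voxel_p`, `alpha` | 0.05, 0.05 | voxel threshold (two-sided) and cluster FWE level |
| `n_iterations` | 1000 | Monte Carlo null volumes |
| `connectivity` | 26 | cluster neighbourhood (6/18/26) |

## Known limitations

* The Monte Carlo null assumes stationary Gaussian smoothness; heavy-tailed
  or nonstationary real data can defeat it, which is a known limitation of
  the convention itself, not of this implementation.
* The composite-Z reference population is the control group by default;
  z-scoring against the whole sample changes the composites' location but
  not group contrasts.
* Distances are Euclidean in a common reference space; they approximate but
  understate anatomical (fibre) distance.
* `pairwise_distance_mm` and the bin geometry assume one shared grid for
  all subjects; subject-specific warps are out of scope.
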