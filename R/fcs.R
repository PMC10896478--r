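#' Connectivity analysis parameters
#'
#' Parameters of the voxel-wise functional connectivity strength (FCS)
#' computation: the positive-correlation threshold `r0` below which edges are
#' discarded as noise, and the Euclidean-distance binning used for the
#' distance-resolved decomposition. Defaults reproduce the standard setup:
#' r0 = 0.2, 18 half-open bins of 10 mm spanning 0-180 mm, short/long split
#' at 100 mm.
#'
#' @param r0 correlation threshold in `[0, 1)`; only `r_ij > r0` (strict)
#'   contributes.
#' @param bin_width_mm width of each distance bin (mm).
#' @param n_bins number of bins.
#' @param distance_max_mm upper end of the binned range;
#'   must equal `n_bins * bin_width_mm`.
#' @param short_long_cut_mm boundary between short- and long-range
#'   aggregates; must lie on a bin edge.
#' @return Object of class `connectivity_params`.
#' @export
connectivity_params <- function(r0 = 0.2, bin_width_mm = 10, n_bins = 18L,
                                distance_max_mm = 180, short_long_cut_mm = 100) {
  if (r0 < 0 || r0 >= 1) stop("r0 must lie in [0, 1)")
  if (bin_width_mm <= 0 || n_bins < 1) stop("bin_width_mm and n_bins must be positive")
  if (abs(n_bins * bin_width_mm - distance_max_mm) > 1e-9)
    stop("distance_max_mm must equal n_bins * bin_width_mm")
  edges <- seq(0, distance_max_mm, by = bin_width_mm)
  if (min(abs(edges - short_long_cut_mm)) > 1e-9)
    stop("short_long_cut_mm must be a bin boundary")
  structure(list(r0 = r0, bin_width_mm = bin_width_mm, n_bins = as.integer(n_bins),
                 distance_max_mm = distance_max_mm,
                 short_long_cut_mm = short_long_cut_mm, bin_edges_mm = edges),
            class = "connectivity_params")
}

## rows standardized so that tcrossprod gives Pearson correlations;
## zero-variance voxels become all-zero rows (correlation defined as 0)
standardize_rows <- function(X) {
  X <- X - rowMeans(X)
  nrm <- sqrt(rowSums(X^2))
  flat <- nrm < 1e-12
  nrm[flat] <- 1
  X <- X / nrm
  X[flat, ] <- 0
  attr(X, "zero_variance") <- which(flat)
  X
}

fisher_z <- function(r) atanh(pmin(r, 1 - 1e-7))

#' Voxel-wise functional connectivity strength (weighted degree centrality)
#'
#' For every in-mask voxel i computes
#' `FCS(i) = 1/(N_voxels - 1) * sum_{j != i, r_ij > r0} z_ij`,
#' where `r_ij` is the Pearson correlation between the time courses of
#' voxels i and j and `z_ij = atanh(r_ij)` its Fisher Z transform
#' (correlations are capped at `1 - 1e-7` before the transform so perfectly
#' correlated voxel pairs stay finite). Only positive correlations above the
#' strict threshold `r0` contribute, so all FCS values are nonnegative.
#' The correlation matrix is streamed in voxel blocks and never materialized
#' in full; results are exactly independent of the block size.
#'
#' Zero-variance voxels are assigned correlation 0 with every other voxel
#' (hence FCS 0) and are reported in the `"zero_variance"` attribute.
#'
#' @param series a [bold_series()] whose rows follow `grid`'s in-mask order.
#' @param grid a [volume_grid()] with at least 2 in-mask voxels.
#' @param params a [connectivity_params()].
#' @param block_size number of voxels per streamed block (default 512).
#' @return Numeric vector of FCS values (one per in-mask voxel) with
#'   attributes `params` and `zero_variance`.
#' @export
compute_fcs <- function(series, grid, params = connectivity_params(),
                        block_size = 512L) {
  pre <- fcs_preflight(series, grid)
  out <- numeric(grid$n_voxels)
  for (block in pre$blocks(block_size)) {
    W <- fcs_block_weights(pre$X, block, params$r0)
    out[block] <- rowSums(W) / (grid$n_voxels - 1)
  }
  attr(out, "params") <- params
  attr(out, "zero_variance") <- attr(pre$X, "zero_variance")
  out
}

fcs_preflight <- function(series, grid, min_timepoints = 2L) {
  stopifnot(inherits(series, "bold_series"), inherits(grid, "volume_grid"))
  if (grid$n_voxels < 2L) stop("FCS needs at least 2 in-mask voxels")
  if (nrow(series$data) != grid$n_voxels)
    stop("series rows (", nrow(series$data), ") must equal mask voxel count (",
         grid$n_voxels, ")")
  if (ncol(series$data) < min_timepoints) stop("too few timepoints")
  X <- standardize_rows(series$data)
  blocks <- function(block_size) {
    block_size <- max(1L, as.integer(block_size))
    split(seq_len(grid$n_voxels),
          ceiling(seq_len(grid$n_voxels) / block_size))
  }
  list(X = X, blocks = blocks)
}

## Fisher-Z weights of one voxel block against all voxels:
## z_ij * 1[r_ij > r0], self-pairs zeroed
fcs_block_weights <- function(X, block, r0) {
  R <- tcrossprod(X[block, , drop = FALSE], X)
  W <- fisher_z(R) * (R > r0)
  W[cbind(seq_along(block), block)] <- 0
  W
}

#' Distance-binned functional connectivity strength
#'
#' Decomposes each voxel's FCS across Euclidean-distance bins: bin k collects
#' `z_ij` over neighbours j with `r_ij > r0` whose distance `D_ij` satisfies
#' `bin_width*(k-1) <= D_ij < bin_width*k` (half-open bins). Every bin map
#' uses the same `1/(N_voxels - 1)` normalization as the full-range FCS, so
#' the bin maps sum exactly to the full-range map at every voxel. A pair at
#' exactly `distance_max_mm` (impossible when that value strictly exceeds the
#' mask diameter) is assigned to the last bin; pairs beyond it fall in no
#' bin.
#'
#' @inheritParams compute_fcs
#' @return Object of class `binned_fcs`: list with `values` (voxels x bins
#'   matrix), `bin_edges_mm`, `bin_masks` (voxels x bins logical; TRUE when
#'   the voxel has at least one in-mask neighbour in that bin, whatever its
#'   correlation), `params`, and `zero_variance`.
#' @export
compute_binned_fcs <- function(series, grid, params = connectivity_params(),
                               block_size = 512L) {
  pre <- fcs_preflight(series, grid)
  nb <- params$n_bins
  vals <- matrix(0, grid$n_voxels, nb)
  bmask <- matrix(FALSE, grid$n_voxels, nb)
  blocks <- pre$blocks(block_size)
  bs <- bin_structure(grid, params, blocks)
  for (bi in seq_along(blocks)) {
    block <- blocks[[bi]]
    W <- fcs_block_weights(pre$X, block, params$r0)
    st <- bs[[bi]]
    sums <- rowsum(W[st$sel], st$grp)        # one pass over all binned pairs
    vblock <- matrix(0, length(block), nb)
    vblock[as.integer(rownames(sums))] <- sums
    vals[block, ] <- vblock
    bmask[block, ] <- st$bin_mask
  }
  vals <- vals / (grid$n_voxels - 1)
  structure(list(values = vals, bin_edges_mm = params$bin_edges_mm,
                 bin_masks = bmask, params = params,
                 zero_variance = attr(pre$X, "zero_variance")),
            class = "binned_fcs")
}

## Distance-bin geometry per streamed block, memoised on the grid: for block
## voxels i and all voxels j, the linear positions of pairs falling in a bin
## (self-pairs and pairs beyond distance_max excluded; a pair at exactly
## distance_max joins the last bin) and their (row-within-block, bin) group
## id for a single-pass rowsum. Subject-independent, so one cohort pays the
## distance computation once.
bin_structure <- function(grid, params, blocks) {
  key <- paste("bins", length(blocks), length(blocks[[1]]), params$n_bins,
               signif(params$bin_width_mm, 10), signif(params$distance_max_mm, 10),
               sep = "_")
  bs <- grid$cache[[key]]
  if (!is.null(bs)) return(bs)
  nb <- params$n_bins
  bs <- lapply(blocks, function(block) {
    D <- block_distances_mm(grid, block)
    B <- findInterval(D, params$bin_edges_mm, rightmost.closed = TRUE)
    dim(B) <- dim(D)
    B[cbind(seq_along(block), block)] <- 0L   # self-pairs carry no bin
    B[B > nb] <- 0L                           # beyond distance_max: no bin
    sel <- which(B > 0L)
    nr <- length(block)
    grp <- ((sel - 1L) %% nr + 1L) + (B[sel] - 1L) * nr
    bin_mask <- matrix(tabulate(grp, nbins = nr * nb) > 0L, nr, nb)
    list(sel = sel, grp = grp, bin_mask = bin_mask)
  })
  grid$cache[[key]] <- bs
  bs
}

#' Short- and long-range FCS aggregates
#'
#' Sums distance-bin FCS maps below and at/above the cut (default 100 mm)
#' into a short-range and a long-range map. Because all bins share one
#' normalization, short + long equals the full-range FCS at every voxel.
#'
#' @param binned a [compute_binned_fcs()] result.
#' @param cut_mm the split distance; must be one of the bin edges.
#' @return List with numeric vectors `short` and `long`, and the per-range
#'   analysis masks `short_mask` / `long_mask` (voxels with at least one
#'   candidate neighbour in the range).
#' @export
aggregate_range <- function(binned, cut_mm = binned$params$short_long_cut_mm) {
  stopifnot(inherits(binned, "binned_fcs"))
  edges <- binned$bin_edges_mm
  if (min(abs(edges - cut_mm)) > 1e-9)
    stop("cut_mm (", cut_mm, ") must be one of the bin edges")
  lower <- which(edges[-length(edges)] < cut_mm - 1e-9)
  upper <- setdiff(seq_len(ncol(binned$values)), lower)
  sum_bins <- function(k) {
    if (length(k) == 0L) numeric(nrow(binned$values))
    else rowSums(binned$values[, k, drop = FALSE])
  }
  any_bins <- function(k) {
    if (length(k) == 0L) logical(nrow(binned$values))
    else rowSums(binned$bin_masks[, k, drop = FALSE]) > 0
  }
  list(short = sum_bins(lower), long = sum_bins(upper),
       short_mask = any_bins(lower), long_mask = any_bins(upper),
       cut_mm = cut_mm)
}
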