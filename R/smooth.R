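## Volumetric Gaussian smoothing via zero-padded FFT convolution.
##
## Kernels are separable Gaussians parameterised by FWHM in mm per axis
## (sigma = fwhm / (2 sqrt(2 log 2))). Kernel FFTs (and the squared-kernel
## FFTs needed for exact variance maps of smoothed white noise) are cached
## per (grid dims, voxel size, fwhm) because the Monte Carlo cluster
## calibration smooths thousands of volumes on one grid.

.smooth_cache <- new.env(parent = emptyenv())

fwhm_to_sigma <- function(fwhm_mm) fwhm_mm / (2 * sqrt(2 * log(2)))

smooth_plan <- function(dims, voxel_size_mm, fwhm_mm) {
  fwhm_mm <- rep(as.numeric(fwhm_mm), length.out = 3L)
  key <- paste(c(dims, signif(voxel_size_mm, 10), signif(fwhm_mm, 10)), collapse = "_")
  plan <- .smooth_cache[[key]]
  if (!is.null(plan)) return(plan)
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / voxel_size_mm
  halfw <- pmax(1L, as.integer(ceiling(4 * sigma_vox)))
  pad <- sapply(dims + 2L * halfw, stats::nextn, factors = c(2L, 3L, 5L))
  k1 <- lapply(1:3, function(a) {
    ## kernel sampled on the circular padded axis, centred at index 1
    x <- c(0:(pad[a] %/% 2), -((pad[a] - 1) %/% 2):-1)
    k <- if (sigma_vox[a] < 1e-8) as.numeric(x == 0) else exp(-x^2 / (2 * sigma_vox[a]^2))
    k / sum(k)
  })
  kern <- outer(outer(k1[[1]], k1[[2]]), k1[[3]])
  dim(kern) <- pad
  plan <- list(pad = pad, dims = dims,
               K = stats::fft(kern), K2 = stats::fft(kern^2))
  .smooth_cache[[key]] <- plan
  plan
}

conv_gauss <- function(vol, plan, squared = FALSE) {
  p <- array(0, dim = plan$pad)
  d <- plan$dims
  p[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- vol
  K <- if (squared) plan$K2 else plan$K
  s <- Re(stats::fft(stats::fft(p) * K, inverse = TRUE)) / prod(plan$pad)
  s[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
}

## mask-weighted smoothing helper objects for one grid + fwhm
mask_smooth_plan <- function(grid, fwhm_mm) {
  plan <- smooth_plan(grid$dim, grid$voxel_size_mm, fwhm_mm)
  key <- paste0("m_", paste(signif(c(grid$dim, grid$voxel_size_mm,
                                     rep(fwhm_mm, length.out = 3)), 10), collapse = "_"),
                "_", grid$n_voxels)
  mp <- .smooth_cache[[key]]
  if (is.null(mp)) {
    m <- array(0, grid$dim); m[grid$idx] <- 1
    sm <- conv_gauss(m, plan)
    sm2 <- conv_gauss(m, plan, squared = TRUE)
    denom <- pmax(sm, 1e-12)
    ## sd of mask-weighted smoothed unit white noise at each in-mask voxel
    sd_map <- sqrt(pmax(sm2[grid$idx], 0)) / denom[grid$idx]
    mp <- list(plan = plan, smoothed_mask = denom, sd_map = sd_map)
    .smooth_cache[[key]] <- mp
  }
  mp
}

#' Smooth an in-mask map with a Gaussian kernel
#'
#' Mask-weighted volumetric Gaussian smoothing: the map is embedded in the
#' full grid with zeros outside the mask, convolved with a Gaussian of the
#' requested FWHM (sigma = fwhm / (2 sqrt(2 log 2)) per axis, in mm), and
#' renormalized inside the mask by the smoothed mask indicator so that
#' boundary voxels are not dimmed by the zero exterior. Constant maps are
#' preserved exactly everywhere in the mask.
#'
#' @param values numeric vector of in-mask voxel values (grid order), or a
#'   matrix with one map per row (all smoothed with one cached kernel).
#' @param grid a [volume_grid()].
#' @param fwhm_mm full width at half maximum in mm (scalar or per-axis);
#'   default 6. Values below the voxel size are honoured but noted, the
#'   kernel then approaches a delta.
#' @return Smoothed values, same shape as `values`.
#' @export
smooth_map <- function(values, grid, fwhm_mm = 6) {
  stopifnot(inherits(grid, "volume_grid"))
  if (any(fwhm_mm < 0)) stop("fwhm_mm must be nonnegative")
  mp <- mask_smooth_plan(grid, fwhm_mm)
  one <- function(v) {
    vol <- array(0, grid$dim)
    vol[grid$idx] <- v
    conv_gauss(vol, mp$plan)[grid$idx] / mp$smoothed_mask[grid$idx]
  }
  if (is.matrix(values)) {
    stopifnot(ncol(values) == grid$n_voxels)
    t(apply(values, 1L, one))
  } else {
    stopifnot(length(values) == grid$n_voxels)
    one(values)
  }
}

#' Simulate one smoothed, standardized null field
#'
#' White noise on the mask, mask-weighted Gaussian smoothing, then
#' voxel-wise standardization by the exact standard deviation of the
#' smoothing operator, so every in-mask voxel is N(0,1) regardless of its
#' distance to the mask edge. This is the null model used by
#' [monte_carlo_cluster_threshold()]; it is exported so that calibration
#' studies can draw from exactly the same distribution.
#'
#' @param grid a [volume_grid()].
#' @param fwhm_mm Gaussian smoothness (scalar or per-axis, mm).
#' @return Numeric vector, one standardized value per in-mask voxel.
#' @export
smoothed_null_field <- function(grid, fwhm_mm) {
  mp <- mask_smooth_plan(grid, fwhm_mm)
  e <- array(0, grid$dim)
  e[grid$idx] <- stats::rnorm(grid$n_voxels)
  s <- conv_gauss(e, mp$plan)[grid$idx] / mp$smoothed_mask[grid$idx]
  s / mp$sd_map
}
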