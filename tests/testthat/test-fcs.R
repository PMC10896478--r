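# construct three series with exact pairwise correlations using an
# orthonormal basis: x1 = u, x2 = r*u + sqrt(1-r^2)*v, x3 = w
exact_corr_series <- function(nt = 32, r = 0.5) {
  set.seed(42)
  B <- qr.Q(qr(cbind(rnorm(nt), rnorm(nt), rnorm(nt), rep(1, nt))))[, 1:3]
  # columns of B are orthonormal; make them exactly mean-zero by projecting
  B <- qr.Q(qr(scale(B, scale = FALSE)))
  x1 <- B[, 1]
  x2 <- r * B[, 1] + sqrt(1 - r^2) * B[, 2]
  x3 <- B[, 3]
  rbind(x1, x2, x3)
}

three_voxel_grid <- function() {
  m <- array(FALSE, c(3, 1, 1)); m[] <- TRUE
  volume_grid(m, 3)
}

test_that("FCS matches the closed form on three voxels with known correlations", {
  g <- three_voxel_grid()
  X <- exact_corr_series(r = 0.5)
  s <- bold_series(X, 2)
  f <- compute_fcs(s, g)
  # r12 = 0.5 -> z = atanh(0.5) shared by voxels 1,2; voxel 3 uncorrelated
  expect_equal(f[1], atanh(0.5) / 2, tolerance = 1e-10)
  expect_equal(f[2], atanh(0.5) / 2, tolerance = 1e-10)
  expect_equal(f[3], 0)
})

test_that("correlations at or below r0 contribute nothing (strict threshold)", {
  g <- three_voxel_grid()
  # mutually orthogonal series: all r = 0
  X <- exact_corr_series(r = 0)
  expect_equal(as.numeric(compute_fcs(bold_series(X, 2), g)), c(0, 0, 0))
  # a pair just below r0 = 0.2 is excluded by the strict inequality ...
  X2 <- exact_corr_series(r = 0.2 - 1e-9)
  expect_equal(as.numeric(compute_fcs(bold_series(X2, 2), g)), c(0, 0, 0))
  # ... and just above it contributes
  X3 <- exact_corr_series(r = 0.2 + 1e-6)
  expect_gt(compute_fcs(bold_series(X3, 2), g)[1], 0)
})

test_that("streamed FCS and binned FCS equal dense oracles over seeds and blocks", {
  params <- connectivity_params()
  for (seed in 1:5) {
    g <- tiny_grid()  # 60 voxels <= 100
    s <- random_series(g, nt = 50, seed = seed)
    oracle <- dense_fcs_oracle(s, g)
    oracle_bins <- dense_binned_oracle(s, g, params)
    for (bs in c(1, 7, 64, g$n_voxels)) {
      f <- compute_fcs(s, g, params, block_size = bs)
      expect_lt(max(abs(f - oracle)), 1e-10)
      b <- compute_binned_fcs(s, g, params, block_size = bs)
      expect_lt(max(abs(b$values - oracle_bins)), 1e-10)
    }
    # conservation: bin sums reproduce the full-range map
    b <- compute_binned_fcs(s, g, params)
    f <- compute_fcs(s, g, params)
    expect_lt(max(abs(rowSums(b$values) - f)) / max(f), 1e-9)
    expect_true(all(f >= 0), info = "FCS positivity")
    expect_true(all(b$values >= 0))
  }
})

test_that("raising r0 never increases any voxel's FCS", {
  g <- tiny_grid()
  s <- random_series(g, nt = 40, seed = 9)
  f_lo <- compute_fcs(s, g, connectivity_params(r0 = 0.1))
  f_mid <- compute_fcs(s, g, connectivity_params(r0 = 0.2))
  f_hi <- compute_fcs(s, g, connectivity_params(r0 = 0.4))
  expect_true(all(f_mid <= f_lo + 1e-12))
  expect_true(all(f_hi <= f_mid + 1e-12))
})

test_that("a single bin covering the whole range reproduces full-range FCS", {
  g <- tiny_grid()
  s <- random_series(g, nt = 45, seed = 2)
  p1 <- connectivity_params(bin_width_mm = 180, n_bins = 1,
                            short_long_cut_mm = 180)
  b <- compute_binned_fcs(s, g, p1)
  f <- compute_fcs(s, g, p1)
  expect_equal(as.numeric(b$values[, 1]), as.numeric(f), tolerance = 1e-12)
})

test_that("zero-variance voxels are flagged and never contribute", {
  g <- three_voxel_grid()
  X <- exact_corr_series(r = 0.9)
  X[3, ] <- 5  # constant voxel
  f <- compute_fcs(bold_series(X, 2), g)
  expect_equal(as.integer(attr(f, "zero_variance")), 3L)
  expect_equal(as.numeric(f[3]), 0)
  expect_equal(as.numeric(f[1]), atanh(0.9) / 2, tolerance = 1e-10)
})

test_that("perfectly correlated voxels stay finite through the Fisher-Z clamp", {
  m <- array(TRUE, c(2, 1, 1))
  g <- volume_grid(m, 3)
  x <- rnorm(30)
  f <- compute_fcs(bold_series(rbind(x, x), 2), g)
  expect_true(all(is.finite(f)))
  expect_equal(unname(f[1]), atanh(1 - 1e-7), tolerance = 1e-6)
})

test_that("short/long aggregation conserves the full map and respects the cut", {
  g <- tiny_grid(shape = c(12, 6, 5), semi = c(5.5, 2.6, 2.2))
  s <- random_series(g, nt = 50, seed = 4)
  params <- connectivity_params()
  b <- compute_binned_fcs(s, g, params)
  f <- compute_fcs(s, g, params)
  agg <- aggregate_range(b, 100)
  expect_lt(max(abs(agg$short + agg$long - f)) / max(f), 1e-9)
  # cut at distance_max puts everything in short
  agg2 <- aggregate_range(b, 180)
  expect_equal(agg2$long, numeric(g$n_voxels))
  expect_equal(agg2$short, as.numeric(f), tolerance = 1e-12)
  # cut must be a bin edge
  expect_error(aggregate_range(b, 95), "bin edge")
  # default bins: cut 100 separates bins 1-10 from 11-18
  expect_equal(agg$short, rowSums(b$values[, 1:10]), tolerance = 1e-12)
  expect_equal(agg$long, rowSums(b$values[, 11:18]), tolerance = 1e-12)
})

test_that("bin masks mark exactly the voxels with a candidate neighbour in range", {
  g <- tiny_grid(shape = c(12, 6, 5), semi = c(5.5, 2.6, 2.2))
  s <- random_series(g, nt = 30, seed = 6)
  b <- compute_binned_fcs(s, g, connectivity_params())
  D <- as.matrix(dist(g$coords_mm))
  diag(D) <- NA
  for (k in c(1, 2, 3, 4)) {
    expected <- apply(D, 1, function(d)
      any(d >= 10 * (k - 1) & d < 10 * k, na.rm = TRUE))
    expect_identical(unname(b$bin_masks[, k]), unname(expected))
  }
})

test_that("map smoothing preserves constants and realizes the requested FWHM", {
  g <- make_mask(simulation_config(grid_shape = c(25, 25, 25),
                                   mask_semi_axes = c(11, 11, 11)))
  # constant field unchanged everywhere in the mask (mask-weighted smoothing)
  expect_lt(max(abs(smooth_map(rep(2.5, g$n_voxels), g, 6) - 2.5)), 1e-10)
  # impulse response has FWHM 6 mm (+- half a voxel, grid quantization)
  ctr <- which.min(rowSums((g$coords_mm - 36)^2))
  v <- numeric(g$n_voxels); v[ctr] <- 1
  sm <- smooth_map(v, g, 6)
  for (a in 1:3) {
    onaxis <- which(apply(g$ijk[, -a, drop = FALSE], 1, function(r)
      all(r == g$ijk[ctr, -a])))
    prof <- sm[onaxis]
    x <- g$coords_mm[onaxis, a]
    # tolerance on the half-max comparison: the 6 mm kernel puts grid points
    # exactly at half maximum, where float round-off would otherwise flip them
    width <- diff(range(x[prof >= max(prof) / 2 * (1 - 1e-9)]))
    expect_gte(width, 6 - 1.6)
    expect_lte(width, 6 + 1.6)
  }
  # near-zero FWHM approaches the identity
  expect_equal(smooth_map(v, g, 1e-6), v, tolerance = 1e-8)
})
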