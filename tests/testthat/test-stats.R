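make_design <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(group = rep(c(1, 0), length.out = n), age = rnorm(n, 68, 9),
             sex = rbinom(n, 1, 0.4), education = rnorm(n, 11, 3))
}

test_that("voxelwise ANCOVA matches lm() on single voxels", {
  n <- 12L
  des <- make_design(n, seed = 2)
  set.seed(3)
  y <- rnorm(n) + 0.8 * des$group + 0.02 * des$age
  st <- voxelwise_ancova(matrix(y, ncol = 1), des)
  ref <- summary(lm(y ~ group + age + sex + education, data = des))
  expect_equal(st$t[1], ref$coefficients["group", "t value"], tolerance = 1e-8)
  expect_identical(st$df, n - 5L)
  expect_equal(st$f[1], ref$coefficients["group", "t value"]^2, tolerance = 1e-8)
})

test_that("an exact null construction gives t = 0 everywhere", {
  n <- 10
  des <- make_design(n)
  # maps determined entirely by covariates, no group effect, no noise
  maps <- outer(des$age, c(1, 2, 3)) + outer(des$education, c(0.5, 0, 1))
  st <- voxelwise_ancova(maps, des)
  expect_lt(max(abs(st$t)), 1e-6)
})

test_that("duplicating every subject strictly increases |t| without changing sign", {
  n <- 14
  des <- make_design(n, seed = 5)
  set.seed(6)
  maps <- matrix(rnorm(n * 5), n, 5) + des$group %o% rep(0.7, 5)
  st1 <- voxelwise_ancova(maps, des)
  st2 <- voxelwise_ancova(rbind(maps, maps), rbind(des, des))
  expect_true(all(abs(st2$t) > abs(st1$t)))
  expect_true(all(sign(st2$t) == sign(st1$t)))
})

test_that("collinear designs are refused with the offending column named", {
  n <- 12
  des <- make_design(n, seed = 7)
  des$score <- des$age  # behavioural score identical to a covariate
  expect_error(
    voxelwise_behaviour_regression(matrix(rnorm(n * 3), n, 3), des),
    "collinear")
  expect_error(voxelwise_ancova(matrix(rnorm(4 * 3), 4, 3), make_design(4)),
               "fewer subjects")
})

test_that("smoothness estimation recovers the applied kernel and is monotone", {
  g <- make_mask(simulation_config(grid_shape = c(24, 24, 20),
                                   mask_semi_axes = c(10, 10, 8)))
  set.seed(31)
  maps6 <- t(replicate(10, smoothed_null_field(g, 6)))
  fw6 <- estimate_smoothness(maps6, g)
  expect_true(all(fw6 >= 5 & fw6 <= 7))
  maps9 <- t(replicate(10, smoothed_null_field(g, 9)))
  fw9 <- estimate_smoothness(maps9, g)
  expect_true(all(fw9 > fw6))
  # white noise clips at one voxel size, within 20%
  white <- matrix(rnorm(10 * g$n_voxels), 10)
  fww <- estimate_smoothness(white, g)
  expect_true(all(abs(fww - 3) <= 0.6))
  expect_true(all(attr(fww, "clipped")))
})

test_that("Monte Carlo extent threshold obeys its quantile limits", {
  g <- make_mask(simulation_config(grid_shape = c(14, 14, 12),
                                   mask_semi_axes = c(6, 6, 5)))
  base <- function(alpha) monte_carlo_cluster_threshold(
    g, 6, cluster_correction_params(alpha = alpha, n_iterations = 200), seed = 4)
  t10 <- base(0.10); t05 <- base(0.05); t01 <- base(0.01)
  expect_lte(t10$extent_voxels, t05$extent_voxels)
  expect_lte(t05$extent_voxels, t01$extent_voxels)
  # alpha -> 1: the threshold collapses to the bottom of the null max-size
  # distribution, so almost any observed cluster passes
  t99 <- monte_carlo_cluster_threshold(
    g, 6, cluster_correction_params(alpha = 0.99, n_iterations = 200), seed = 4)
  expect_lte(t99$extent_voxels, t10$extent_voxels)
  expect_lte(t99$extent_voxels, sort(t99$max_sizes)[3])
  expect_equal(t05$extent_mm3, t05$extent_voxels * 27)
  # reproducible under the seed
  expect_identical(base(0.05)$max_sizes, t05$max_sizes)
})

test_that("cluster extraction honours extent, sign and connectivity semantics", {
  m <- array(TRUE, c(10, 10, 4))
  g <- volume_grid(m, 3)
  z <- numeric(g$n_voxels)
  cc <- cluster_correction_params(connectivity = 26)
  # empty map -> empty table
  expect_identical(nrow(extract_clusters(z, g, 0, cc, df = Inf)), 0L)
  # one 10-voxel and one 3-voxel blob, extent threshold 5 -> only the 10 survives
  blob10 <- which(g$ijk[, 1] <= 5 & g$ijk[, 2] == 2 & g$ijk[, 3] <= 2)[1:10]
  blob3 <- which(g$ijk[, 1] >= 8 & g$ijk[, 2] == 8 & g$ijk[, 3] == 1)[1:3]
  z[blob10] <- 5; z[blob3] <- -5
  tab <- extract_clusters(z, g, 5, cc, df = Inf)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$n_voxels, 10L)
  expect_identical(tab$sign, "positive")
  expect_equal(tab$volume_mm3, 270)
  # exactly at the extent threshold a cluster is rejected (strict >)
  expect_identical(nrow(extract_clusters(z, g, 10, cc, df = Inf)), 0L)
  # diagonal chain: one cluster under 26-connectivity, several under 6
  z2 <- numeric(g$n_voxels)
  diag_vox <- sapply(1:4, function(i)
    which(g$ijk[, 1] == i & g$ijk[, 2] == i & g$ijk[, 3] == min(i, 4)))
  z2[diag_vox] <- 5
  t26 <- extract_clusters(z2, g, 0, cluster_correction_params(connectivity = 26),
                          df = Inf)
  t6 <- extract_clusters(z2, g, 0, cluster_correction_params(connectivity = 6),
                         df = Inf)
  expect_identical(nrow(t26), 1L)
  expect_gt(nrow(t6), 1L)
})

test_that("negative and positive excursions are never merged into one cluster", {
  m <- array(TRUE, c(8, 3, 3))
  g <- volume_grid(m, 3)
  z <- numeric(g$n_voxels)
  z[g$ijk[, 1] <= 3] <- 4
  z[g$ijk[, 1] >= 4 & g$ijk[, 1] <= 6] <- -4
  tab <- extract_clusters(z, g, 0, cluster_correction_params(), df = Inf)
  expect_identical(sort(tab$sign), c("negative", "positive"))
  expect_identical(sum(tab$n_voxels), sum(z != 0))
})

test_that("behaviour regression recovers a planted score effect", {
  n <- 24
  set.seed(41)
  des <- data.frame(score = rnorm(n), age = rnorm(n, 68, 8),
                    sex = rbinom(n, 1, 0.5), education = rnorm(n, 11, 3))
  v <- 40
  planted <- 1:10
  maps <- matrix(rnorm(n * v, sd = 0.5), n, v)
  maps[, planted] <- maps[, planted] + des$score %o% rep(1, length(planted))
  st <- voxelwise_behaviour_regression(maps, des)
  tcrit <- qt(0.975, st$df)
  expect_gte(mean(st$t[planted] > tcrit), 0.8)
  expect_lte(mean(abs(st$t[-planted]) > tcrit), 0.25)
})
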