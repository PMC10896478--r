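test_that("subject simulation is bit-reproducible given the subject seed", {
  cfg <- simulation_config(grid_shape = c(10, 10, 8), mask_semi_axes = c(4.4, 4.4, 3.4),
                           hub_centers = rbind(c(5, 5, 4)), n_timepoints = 60,
                           smooth_noise_fwhm_mm = 0)
  g <- make_mask(cfg)
  a <- simulate_subject_bold(cfg, "patient", 123, g)
  b <- simulate_subject_bold(cfg, "patient", 123, g)
  expect_identical(a$series$data, b$series$data)
  c <- simulate_subject_bold(cfg, "patient", 124, g)
  expect_false(identical(a$series$data, c$series$data))
})

test_that("hub centres outside the mask are rejected", {
  cfg <- simulation_config(grid_shape = c(10, 10, 8), mask_semi_axes = c(3, 3, 2.5),
                           hub_centers = rbind(c(1, 1, 1)))
  expect_error(make_mask(cfg), NA)
  expect_error(simulate_subject_bold(cfg, "control", 1), "outside the mask")
})

test_that("attenuation 1 yields identical patient and control generating models", {
  cfg <- long_range_config(seed = 3, long_range_attenuation = 1)
  g <- make_mask(cfg)
  p <- simulate_subject_bold(cfg, "patient", 55, g)
  c <- simulate_subject_bold(cfg, "control", 55, g)
  expect_identical(p$ground_truth$group_coupling, c$ground_truth$group_coupling)
  expect_identical(p$series$data, c$series$data)  # same seed, same model
})

test_that("patient attenuation only touches couplings beyond the long-range cut", {
  cfg <- long_range_config(seed = 3, long_range_attenuation = 0.5)
  g <- make_mask(cfg)
  p <- simulate_subject_bold(cfg, "patient", 9, g)
  c <- simulate_subject_bold(cfg, "control", 9, g)
  D <- p$ground_truth$hub_distances_mm
  Cp <- p$ground_truth$group_coupling
  Cc <- c$ground_truth$group_coupling
  far <- D > 100
  expect_equal(Cp[!far], Cc[!far])
  expect_equal(Cp[far & upper.tri(D)], 0.5 * Cc[far & upper.tri(D)])
  expect_true(all(diag(Cp) == 1))
  expect_equal(Cp, t(Cp))
})

test_that("two planted hubs reproduce their requested coupling empirically", {
  cfg <- simulation_config(grid_shape = c(40, 8, 8), mask_semi_axes = c(19, 3.4, 3.4),
                           hub_centers = rbind(c(6, 4, 4), c(35, 4, 4)),
                           hub_coupling = 0.8, noise_sd = 1e-4,
                           smooth_noise_fwhm_mm = 0, coupling_gain_sd = 0,
                           n_timepoints = 400)
  g <- make_mask(cfg)
  s <- simulate_subject_bold(cfg, "control", 7, g)
  hub_rows <- apply(s$ground_truth$hub_centers, 1, function(h)
    which(g$ijk[, 1] == h[1] & g$ijk[, 2] == h[2] & g$ijk[, 3] == h[3]))
  r <- cor(s$series$data[hub_rows[1], ], s$series$data[hub_rows[2], ])
  expect_equal(r, 0.8, tolerance = 0.01)  # noise floor 1e-4 only
})

test_that("cohort table is reproducible and demographics match their targets", {
  cfg <- simulation_config(grid_shape = c(10, 10, 8), mask_semi_axes = c(4.4, 4.4, 3.4),
                           hub_centers = rbind(c(5, 5, 4)),
                           n_patients = 40, n_controls = 40, seed = 21)
  t1 <- simulate_cohort_table(cfg)
  t2 <- simulate_cohort_table(cfg)
  expect_identical(t1, t2)
  # pool several cohorts: patient mean age ~65.2, control ~71.0
  ages_p <- c(); ages_c <- c()
  for (s in 1:6) {
    tt <- simulate_cohort_table(simulation_config(
      grid_shape = c(10, 10, 8), mask_semi_axes = c(4.4, 4.4, 3.4),
      hub_centers = rbind(c(5, 5, 4)), n_patients = 40, n_controls = 40,
      seed = 100 + s))
    ages_p <- c(ages_p, tt$age[tt$group == "patient"])
    ages_c <- c(ages_c, tt$age[tt$group == "control"])
  }
  # n = 240 per group: SE ~ 10.1/sqrt(240) ~ 0.65; allow 3 SE
  expect_lt(abs(mean(ages_p) - 65.2), 2)
  expect_lt(abs(mean(ages_c) - 71.0), 1.6)
})

test_that("a null cognition effect leaves scores uncorrelated with hub gain", {
  cors <- sapply(1:8, function(s) {
    tt <- simulate_cohort_table(simulation_config(
      grid_shape = c(10, 10, 8), mask_semi_axes = c(4.4, 4.4, 3.4),
      hub_centers = rbind(c(4, 5, 4), c(7, 5, 4)),
      n_patients = 30, n_controls = 30, cognition_effect = 0, seed = 200 + s))
    cor(tt$information_processing_speed, tt$gain)
  })
  # each correlation is a draw with SE ~ 1/sqrt(57); the mean of 8 must be near 0
  expect_lt(abs(mean(cors)), 3 / sqrt(57 * 8))
})

test_that("planted group disruption lowers patient hub FCS (effect direction)", {
  # subject connectivity gain held fixed so the contrast isolates the
  # long-range attenuation; moderate noise keeps small cohorts informative
  signs <- logical(6)
  params <- connectivity_params()
  for (r in seq_along(signs)) {
    cfg <- long_range_config(seed = 700 + r, n_patients = 6, n_controls = 6,
                             n_timepoints = 120, noise_sd = 0.7,
                             coupling_gain_sd = 0)
    coh <- simulate_cohort(cfg)
    g <- coh$grid
    hubv <- coh$ground_truth$hub_mask
    mn <- sapply(seq_len(nrow(coh$table)), function(i) {
      pp <- preprocess_bold(coh$bold[[i]])
      mean(compute_fcs(pp, g, params)[hubv])
    })
    pat <- coh$table$group == "patient"
    signs[r] <- mean(mn[pat]) < mean(mn[!pat])
  }
  expect_gte(sum(signs), 5)
})

test_that("non-positive-definite coupling requests are repaired and flagged", {
  # three hubs, pairwise coupling 0.9 with one pair attenuated to -0.9 is
  # impossible; push couplings so attenuation breaks positive definiteness
  C <- matrix(c(1, 0.9, 0.9, 0.9, 1, 0.05, 0.9, 0.05, 1), 3)
  rep_ <- fcsconn:::repair_correlation(C)
  expect_true(rep_$repaired)
  ev <- eigen(rep_$C, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_equal(diag(rep_$C), rep(1, 3), tolerance = 1e-8)
  ok <- fcsconn:::repair_correlation(diag(3))
  expect_false(ok$repaired)
})
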