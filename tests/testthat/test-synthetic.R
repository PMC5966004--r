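test_that("cohort generation is deterministic for a fixed seed", {
  cfg <- tiny_cohort_config(seed = 4L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_equal(length(a), length(b))
  for (i in seq_along(a)) {
    expect_identical(a[[i]]$series$maps, b[[i]]$series$maps)
    expect_identical(a[[i]]$mask$labels, b[[i]]$mask$labels)
    expect_identical(a[[i]]$truth, b[[i]]$truth)
  }
  # a different seed changes the data
  c <- generate_cohort(tiny_cohort_config(seed = 5L))
  expect_false(identical(a[[1]]$series$maps, c[[1]]$series$maps))
})

test_that("lesion voxels follow the closed-form rise/washout curve", {
  cfg <- tiny_cohort_config(seed = 8L, n_patients = 1L, lesions_mean = 2)
  d <- generate_cohort(cfg)[[1]]
  lam <- d$truth$lambda_per_s[1]
  tp_s <- cfg$time_to_peak_h * 3600
  for (k in d$truth$lesion_id) {
    vox <- which(d$mask$labels == k)
    a_k <- d$truth$amplitude_MBq[k]
    for (i in seq_along(cfg$schedule_h)) {
      t_s <- cfg$schedule_h[i] * 3600
      expected <- if (t_s < tp_s) {
        a_k * (t_s / tp_s) * exp(-lam * tp_s)
      } else {
        a_k * exp(-lam * t_s)
      }
      expect_equal(unique(d$series$maps[[i]][vox]), expected,
                   tolerance = 1e-12)
    }
  }
  # lesions are disjoint and each has at least one voxel
  expect_equal(sort(unique(as.integer(d$mask$labels[d$mask$labels > 0]))),
               d$truth$lesion_id)
  expect_true(all(d$truth$n_voxels >= 1))
})

test_that("whole-volume activity matches the analytic bookkeeping", {
  cfg <- tiny_cohort_config(seed = 12L)
  cohort <- generate_cohort(cfg)
  reg <- load_default_registry()
  delivered <- reg[["186Re-HEDP"]]
  lam <- effective_lambda_s(delivered)
  retained <- delivered$bone_uptake_fraction * planned_activity(delivered)
  for (d in cohort) {
    total_72 <- sum(d$series$maps[[5]])
    analytic <- retained * exp(-lam * 72 * 3600)
    expect_lt(abs(total_72 / analytic - 1), 0.005)
  }
})

test_that("infeasible lesion packing raises a packing error", {
  cfg <- synthetic_cohort_config(n_patients = 1L, grid_dim = c(10L, 10L, 10L),
                                 lesions_per_patient_mean = 30,
                                 lesions_per_patient_range = c(30L, 30L),
                                 semi_axes_range_vox = c(2, 3), seed = 1L)
  expect_error(generate_cohort(cfg), "packing error")
})

test_that("ground-truth doses scale exactly with administered activity", {
  cfg <- tiny_cohort_config(seed = 21L, n_patients = 1L)
  d <- generate_cohort(cfg)[[1]]
  kernels <- small_kernels(size = 7L)
  reg <- load_default_registry()
  base <- reg[["188Re-HEDP"]]
  doubled <- radiopharmaceutical("188Re-HEDPx2", base$physical_half_life_d,
                                 effective_half_life_d =
                                   base$effective_half_life_d,
                                 bone_uptake_fraction =
                                   base$bone_uptake_fraction,
                                 administered_activity_MBq =
                                   2 * base$administered_activity_MBq)
  g1 <- ground_truth_dose(d, kernels[["188Re"]], base)
  g2 <- ground_truth_dose(d, kernels[["188Re"]], doubled)
  expect_equal(g2$peak_Gy, 2 * g1$peak_Gy, tolerance = 1e-12)

  noisy <- generate_cohort(tiny_cohort_config(seed = 21L, noise_cv = 0.05,
                                              n_patients = 1L))[[1]]
  expect_error(ground_truth_dose(noisy, kernels[["188Re"]]), "noise-free")
})

test_that("log-normal amplitudes are recovered from the dose profile", {
  # amplitudes and peak doses differ by a lesion-geometry factor; with fixed
  # lesion shape the log-dose sigma equals the configured amplitude sigma,
  # and mu shifts by the (common) kernel/integration factor
  cfg <- synthetic_cohort_config(n_patients = 8L, grid_dim = c(48L, 48L, 48L),
                                 lesions_per_patient_mean = 40,
                                 lesions_per_patient_range = c(30L, 60L),
                                 semi_axes_range_vox = c(2, 2),
                                 background_fraction = 0,
                                 amplitude_lnorm_sigma = 0.7, seed = 33L)
  cohort <- generate_cohort(cfg)
  amp <- unlist(lapply(cohort, function(d) d$truth$amplitude_MBq))
  n <- length(amp)
  expect_gte(n, 300)
  fit <- fit_lognormal(amp)
  se_sigma <- 0.7 / sqrt(2 * n)
  expect_lt(abs(fit$sigma - 0.7), 3 * se_sigma)
})

test_that("cohorts round-trip through the on-disk layout", {
  cfg <- tiny_cohort_config(seed = 2L, n_patients = 2L, grid = 24L,
                            lesions_mean = 2)
  cohort <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_equal(length(back), 2L)
  for (i in seq_along(cohort)) {
    expect_equal(back[[i]]$series$times_h, cohort[[i]]$series$times_h)
    for (j in seq_along(cohort[[i]]$series$maps)) {
      expect_equal(back[[i]]$series$maps[[j]], cohort[[i]]$series$maps[[j]],
                   tolerance = 1e-12)
    }
    expect_identical(back[[i]]$mask$labels, cohort[[i]]$mask$labels)
  }
})
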