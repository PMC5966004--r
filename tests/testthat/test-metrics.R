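uniform_dose_fixture <- function(value, dims = c(7, 7, 7), voxel = 4.67) {
  dose <- absorbed_dose_map(array(value, dim = dims), voxel)
  labels <- array(0L, dim = dims)
  labels[3:5, 3:5, 3:5] <- 1L
  list(dose = dose, mask = lesion_mask(labels, voxel))
}

test_that("peak dose averages the lesion maximum with its face neighbours", {
  # uniform field: peak equals the uniform value
  f <- uniform_dose_fixture(4.2)
  expect_equal(peak_dose(f$dose, f$mask, 1), 4.2)

  # isolated hot voxel in a zero field: mean(h, 0 x 6) = h/7
  v <- array(0, dim = c(7, 7, 7)); v[4, 4, 4] <- 7
  dose <- absorbed_dose_map(v, 4.67)
  expect_equal(peak_dose(dose, f$mask, 1), 1)
  # full 26-neighbourhood variant
  expect_equal(peak_dose(dose, f$mask, 1, "full26"), 7 / 27)

  # random field vs an exhaustive scan over lesion voxels
  set.seed(31)
  v <- array(runif(7^3), dim = c(7, 7, 7))
  dose <- absorbed_dose_map(v, 4.67)
  idx <- which(f$mask$labels == 1L)
  top <- idx[which.max(v[idx])]
  pos <- arrayInd(top, c(7, 7, 7))
  nb <- c(v[pos], v[pos[1] - 1, pos[2], pos[3]], v[pos[1] + 1, pos[2], pos[3]],
          v[pos[1], pos[2] - 1, pos[3]], v[pos[1], pos[2] + 1, pos[3]],
          v[pos[1], pos[2], pos[3] - 1], v[pos[1], pos[2], pos[3] + 1])
  expect_equal(peak_dose(dose, f$mask, 1), mean(nb))

  # peak bounded by the 6-neighbour rule
  expect_gte(peak_dose(dose, f$mask, 1), max(v[idx]) / 7)
  expect_lte(peak_dose(dose, f$mask, 1), max(v))

  expect_error(peak_dose(dose, f$mask, 99), "missing lesion")
})

test_that("peak dose drops neighbours outside the volume", {
  v <- array(0, dim = c(5, 5, 5)); v[1, 3, 3] <- 10
  labels <- array(0L, dim = c(5, 5, 5)); labels[1, 3, 3] <- 1L
  dose <- absorbed_dose_map(v, 4.67)
  mask <- lesion_mask(labels, 4.67)
  # only 5 in-volume neighbours remain: mean over 6 values
  expect_equal(peak_dose(dose, mask, 1), 10 / 6)
})

test_that("log-normal fit is maximum likelihood on logs", {
  expect_equal(fit_lognormal(c(3, 3, 3))$mu, log(3))
  expect_equal(fit_lognormal(c(3, 3, 3))$sigma, 0)
  two <- fit_lognormal(c(exp(1), exp(3)))
  expect_equal(two$mu, 2)
  expect_equal(two$sigma, 1)
  expect_error(fit_lognormal(c(1, -1)), "positive")
  expect_error(fit_lognormal(5), "at least 2")

  # parameter recovery from a seeded draw with known truth
  set.seed(77)
  d <- rlnorm(379, meanlog = 2.8, sdlog = 0.7)
  fit <- fit_lognormal(d)
  se_mu <- 0.7 / sqrt(379)
  se_sigma <- 0.7 / sqrt(2 * 379)
  expect_lt(abs(fit$mu - 2.8), 3 * se_mu)
  expect_lt(abs(fit$sigma - 0.7), 3 * se_sigma)

  # cross-check against an independent ML fitter
  ind <- MASS::fitdistr(d, "lognormal")
  expect_equal(fit$mu, unname(ind$estimate["meanlog"]), tolerance = 1e-6)
  expect_equal(fit$sigma, unname(ind$estimate["sdlog"]), tolerance = 1e-6)
})

test_that("cDVH is a valid survival curve of the pooled disease volume", {
  # one lesion, uniform dose: a step at that dose
  f <- uniform_dose_fixture(10)
  cd <- build_cdvh(list(f$dose), list(f$mask))
  expect_equal(covered_fraction(cd, c(0, 5, 10)), c(1, 1, 1))
  expect_equal(covered_fraction(cd, 10.0001), 0)
  expect_equal(d50(cd), 10)

  # two equal-volume lesions at 10 and 20 Gy
  v <- array(0, dim = c(9, 9, 9))
  labels <- array(0L, dim = c(9, 9, 9))
  labels[2:3, 2:3, 2:3] <- 1L; v[2:3, 2:3, 2:3] <- 10
  labels[6:7, 6:7, 6:7] <- 2L; v[6:7, 6:7, 6:7] <- 20
  cd2 <- build_cdvh(list(absorbed_dose_map(v, 4.67)),
                    list(lesion_mask(labels, 4.67)))
  expect_equal(covered_fraction(cd2, c(5, 10, 15, 20)), c(1, 1, 0.5, 0.5))
  expect_equal(covered_fraction(cd2, 21), 0)
  expect_equal(d50(cd2), 20)
  expect_equal(cd2$total_volume_ml, 16 * 4.67^3 / 1000)

  # monotone non-increasing with covered_fraction(0) = 1
  expect_equal(cd2$covered_fraction[1], 1)
  expect_true(all(diff(cd2$covered_fraction) <= 1e-12))

  expect_error(build_cdvh(list(f$dose),
                          list(lesion_mask(array(0L, dim = c(7, 7, 7)), 4.67))),
               "empty cohort")
})

test_that("cDVH and D50 match a sort-based oracle on random cohorts", {
  set.seed(53)
  doses <- list(); masks <- list()
  for (p in 1:3) {
    v <- array(rexp(6^3, rate = 0.1), dim = c(6, 6, 6))
    labels <- array(0L, dim = c(6, 6, 6))
    labels[sample(6^3, 40)] <- sample(1:3, 40, replace = TRUE)
    doses[[p]] <- absorbed_dose_map(v, 4.67)
    masks[[p]] <- lesion_mask(labels, 4.67, sprintf("P%d", p))
  }
  cd <- build_cdvh(doses, masks)
  pooled <- unlist(lapply(1:3, function(p) {
    doses[[p]]$values[masks[[p]]$labels > 0]
  }))
  # oracle: brute-force count at each probe dose
  for (q in stats::quantile(pooled, c(0.1, 0.5, 0.9))) {
    expect_equal(covered_fraction(cd, q), mean(pooled >= q))
  }
  # D50 oracle: largest pooled dose with at least half the voxels at or above
  srt <- sort(pooled, decreasing = TRUE)
  oracle_d50 <- srt[ceiling(length(srt) / 2)]
  expect_equal(d50(cd), oracle_d50)
  # tabulated curve agrees with the exact evaluation on its own grid
  expect_equal(cd$covered_fraction, covered_fraction(cd, cd$dose_Gy))
})

test_that("treatment comparison reports medians and rounded differences", {
  recs <- function(doses) {
    data.frame(patient_id = "P1", lesion_id = seq_along(doses),
               volume_ml = 1, peak_Gy = doses, mean_Gy = doses)
  }
  profiles <- list(D = cohort_dose_profile(recs(c(10, 17.7, 30))),
                   E = cohort_dose_profile(recs(c(5, 10.4, 20))))
  tab <- compare_treatments(profiles, "D")
  expect_equal(tab$pct_diff[tab$plan == "D"], 0)
  expect_equal(tab$pct_diff_unrounded[tab$plan == "E"],
               100 * (10.4 / 17.7 - 1), tolerance = 1e-12)
  expect_equal(tab$pct_diff[tab$plan == "E"], -41)

  # identical profile: exactly zero difference
  profiles2 <- list(D = profiles$D, E = profiles$D)
  tab2 <- compare_treatments(profiles2, "D")
  expect_true(all(tab2$pct_diff == 0))

  # mismatched lesion sets are rejected
  profiles3 <- list(D = profiles$D, E = cohort_dose_profile(recs(c(1, 2))))
  expect_error(compare_treatments(profiles3, "D"), "mismatched lesion sets")
})

test_that("lesion masks round-trip through NIfTI", {
  labels <- array(0L, dim = c(6, 6, 6))
  labels[2:3, 2:3, 2:3] <- 1L
  labels[5, 5, 5] <- 2L
  mask <- lesion_mask(labels, 4.67, "P9")
  path <- withr::local_tempfile(fileext = ".nii")
  write_lesion_mask(mask, path)
  back <- read_lesion_mask(path, "P9")
  expect_identical(back$labels, mask$labels)
  expect_equal(back$voxel_size_mm, mask$voxel_size_mm, tolerance = 1e-6)
})
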