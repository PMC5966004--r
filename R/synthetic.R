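#' Synthetic SPECT-like cohort generator
#'
#' Generates seeded synthetic patient datasets — sequential activity maps,
#' lesion label masks and a delivered treatment plan — with the statistical
#' structure the analysis assumes: ellipsoidal bone lesions with log-normal
#' per-lesion uptake amplitudes, a linear uptake phase followed by
#' monoexponential washout at the delivered plan's effective rate, and a
#' 1/4/24/48/72 h scan schedule. The generator emulates the geometry and
#' kinetics of quantitative bone-agent SPECT; it does not model SPECT physics
#' (collimator blur, attenuation, projection noise) or skeletal anatomy.
#'
#' @name synthetic_cohort
NULL

#' Synthetic cohort configuration
#'
#' Per-voxel time-activity curves rise linearly from zero at administration to
#' the washout curve at `time_to_peak_h`, then decay monoexponentially at the
#' delivered plan's effective rate. Each lesion has a uniform per-voxel
#' amplitude drawn log-normally; amplitudes are rescaled so the whole-volume
#' washout curve extrapolated to t = 0 equals the delivered plan's uptake
#' fraction times its administered activity.
#'
#' @param n_patients number of patients
#' @param grid_dim integer 3-vector of grid extents
#' @param voxel_size_mm isotropic voxel pitch in mm
#' @param lesions_per_patient_mean mean of the truncated Poisson lesion count
#' @param lesions_per_patient_range inclusive bounds on the lesion count
#' @param semi_axes_range_vox range of ellipsoid semi-axes, voxels
#' @param time_to_peak_h uptake time-to-peak in hours; the default 4 h places
#'   the peak at the second scan so both the rising (trapezoid) and washout
#'   (exponential) integration branches are exercised
#' @param amplitude_lnorm_mu,amplitude_lnorm_sigma log-normal parameters of
#'   the per-lesion amplitude distribution (relative scale; rescaled to match
#'   the plan's retained activity)
#' @param background_fraction per-voxel background amplitude as a fraction of
#'   the mean lesion per-voxel amplitude (0 disables background)
#' @param noise_cv coefficient of variation of multiplicative Gaussian noise
#'   applied to every sampled map value (0 = noise-free)
#' @param schedule_h scan times in hours
#' @param patient_mass_kg body mass used for per-kg plans
#' @param normalise_to_retained rescale each patient's amplitude field so the
#'   whole-volume washout curve extrapolated to t = 0 equals the plan's
#'   retained activity (default); `FALSE` keeps the raw log-normal draws,
#'   useful for parameter-recovery studies
#' @param seed integer random seed, recorded in every output
#' @return a list of class `synthetic_cohort_config`
#' @export
synthetic_cohort_config <- function(n_patients = 22L,
                                    grid_dim = c(64L, 64L, 64L),
                                    voxel_size_mm = 4.67,
                                    lesions_per_patient_mean = 17,
                                    lesions_per_patient_range = c(1L, 40L),
                                    semi_axes_range_vox = c(2, 4),
                                    time_to_peak_h = 4,
                                    amplitude_lnorm_mu = 0,
                                    amplitude_lnorm_sigma = 0.7,
                                    background_fraction = 0.05,
                                    noise_cv = 0,
                                    schedule_h = c(1, 4, 24, 48, 72),
                                    patient_mass_kg = 70,
                                    normalise_to_retained = TRUE,
                                    seed = 1L) {
  stopifnot(n_patients >= 1, length(grid_dim) == 3L, all(grid_dim >= 8L),
            voxel_size_mm > 0, lesions_per_patient_mean > 0,
            length(lesions_per_patient_range) == 2L,
            lesions_per_patient_range[1] >= 1L,
            diff(lesions_per_patient_range) >= 0,
            length(semi_axes_range_vox) == 2L, semi_axes_range_vox[1] >= 1,
            time_to_peak_h > 0, amplitude_lnorm_sigma >= 0,
            background_fraction >= 0, noise_cv >= 0,
            length(schedule_h) >= 2L, all(diff(schedule_h) > 0),
            schedule_h[1] > 0, patient_mass_kg > 0)
  structure(as.list(environment()), class = "synthetic_cohort_config")
}

# truncated Poisson draw by rejection (bounded retries)
rtrunc_pois <- function(mean, range) {
  for (i in 1:1000) {
    k <- stats::rpois(1, mean)
    if (k >= range[1] && k <= range[2]) return(k)
  }
  range[1] + (stats::rpois(1, mean) %% (range[2] - range[1] + 1L))
}

# voxel indices of an axis-aligned ellipsoid; NULL if it leaves the grid
ellipsoid_voxels <- function(centre, semi, grid_dim) {
  lo <- floor(centre - semi); hi <- ceiling(centre + semi)
  if (any(lo < 1) || any(hi > grid_dim)) return(NULL)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  inside <- ((g$x - centre[1]) / semi[1])^2 +
    ((g$y - centre[2]) / semi[2])^2 +
    ((g$z - centre[3]) / semi[3])^2 <= 1
  g <- g[inside, , drop = FALSE]
  (g$z - 1L) * grid_dim[1] * grid_dim[2] + (g$y - 1L) * grid_dim[1] + g$x
}

#' Generate a synthetic patient cohort
#'
#' Deterministic for a fixed configuration (the seed is set internally).
#' Lesions are non-overlapping axis-aligned ellipsoids placed with a one-voxel
#' margin; placement retries are bounded and an infeasible packing raises an
#' error suggesting a larger grid.
#'
#' @param config a `synthetic_cohort_config`
#' @param delivered `radiopharmaceutical` of the delivered plan (defaults to
#'   the Re-186 HEDP entry of [load_default_registry()])
#' @return list of `patient_dataset` objects, each holding `series`
#'   (`scan_series`), `mask` (`lesion_mask`), `plan`, and `truth` (per-lesion
#'   amplitude, washout rate and rise time actually used); the config is
#'   attached as an attribute
#' @export
generate_cohort <- function(config,
                            delivered = load_default_registry()[["186Re-HEDP"]]) {
  stopifnot(inherits(config, "synthetic_cohort_config"),
            inherits(delivered, "radiopharmaceutical"))
  set.seed(config$seed)
  lambda_d <- effective_lambda_s(delivered)
  retained_MBq <- delivered$bone_uptake_fraction *
    planned_activity(delivered, config$patient_mass_kg)
  tp_s <- hours_to_seconds(config$time_to_peak_h)
  t_s <- hours_to_seconds(config$schedule_h)
  mean_amp <- exp(config$amplitude_lnorm_mu +
                    config$amplitude_lnorm_sigma^2 / 2)

  lapply(seq_len(config$n_patients), function(p) {
    gd <- as.integer(config$grid_dim)
    labels <- array(0L, dim = gd)
    occupied <- array(FALSE, dim = gd) # lesions dilated by a 1-voxel margin
    n_lesions <- rtrunc_pois(config$lesions_per_patient_mean,
                             config$lesions_per_patient_range)
    amp <- numeric(n_lesions)
    nvox <- integer(n_lesions)
    for (k in seq_len(n_lesions)) {
      placed <- FALSE
      for (try in 1:200) {
        semi <- stats::runif(3, config$semi_axes_range_vox[1],
                             config$semi_axes_range_vox[2])
        centre <- vapply(1:3, function(a) {
          stats::runif(1, semi[a] + 2, gd[a] - semi[a] - 1)
        }, numeric(1))
        vox <- ellipsoid_voxels(centre, semi, gd)
        margin <- ellipsoid_voxels(centre, semi + 1, gd)
        if (is.null(vox) || length(vox) == 0L || is.null(margin)) next
        if (any(occupied[margin])) next
        labels[vox] <- k
        occupied[margin] <- TRUE
        nvox[k] <- length(vox)
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("packing error: could not place lesion ", k, " of ", n_lesions,
             " after 200 attempts; use a larger grid or fewer/smaller lesions",
             call. = FALSE)
      }
      amp[k] <- stats::rlnorm(1, config$amplitude_lnorm_mu,
                              config$amplitude_lnorm_sigma)
    }
    # per-voxel amplitude field (washout curve extrapolated to t = 0)
    a <- array(0, dim = gd)
    for (k in seq_len(n_lesions)) a[labels == k] <- amp[k]
    if (config$background_fraction > 0) {
      a[labels == 0L] <- config$background_fraction * mean_amp
    }
    # rescale so the whole-volume amplitude sum equals the retained activity
    bg_amp <- if (config$background_fraction > 0) {
      config$background_fraction * mean_amp
    } else 0
    if (isTRUE(config$normalise_to_retained)) {
      scale <- retained_MBq / sum(a)
      a <- a * scale
      amp <- amp * scale
      bg_amp <- bg_amp * scale
    }

    maps <- lapply(seq_along(t_s), function(i) {
      m <- a * tac_shape(t_s[i], tp_s, lambda_d)
      if (config$noise_cv > 0) {
        m <- m * (1 + config$noise_cv * stats::rnorm(length(m)))
        m[m < 0] <- 0
        m <- array(m, dim = gd)
      }
      m
    })
    pid <- sprintf("SYN%03d", p)
    structure(
      list(series = scan_series(config$schedule_h, maps,
                                config$voxel_size_mm, pid),
           mask = lesion_mask(labels, config$voxel_size_mm, pid),
           plan = delivered,
           background_amplitude_MBq = bg_amp,
           truth = data.frame(lesion_id = seq_len(n_lesions),
                              amplitude_MBq = amp,
                              n_voxels = nvox,
                              lambda_per_s = lambda_d,
                              time_to_peak_h = config$time_to_peak_h)),
      class = "patient_dataset", config = config)
  })
}

# normalised TAC shape: linear rise to exp(-lambda tp) at tp, then exp(-lambda t)
tac_shape <- function(t_s, tp_s, lambda) {
  ifelse(t_s < tp_s,
         (t_s / tp_s) * exp(-lambda * tp_s),
         exp(-lambda * t_s))
}

# exact time integral (s) of the extrapolated TAC shape for unit amplitude:
#   delivered shape s(t) times exp((lambda_d - lambda_e) t), washout rate
#   lambda_e after the substitution
tac_integral_exact <- function(tp_s, lambda_d, lambda_e) {
  kap <- lambda_d - lambda_e
  rise_base <- exp(-lambda_d * tp_s) / tp_s
  rise <- if (abs(kap) < 1e-18) {
    rise_base * tp_s^2 / 2
  } else {
    rise_base * (exp(kap * tp_s) * (tp_s / kap - 1 / kap^2) + 1 / kap^2)
  }
  tail <- exp(-lambda_e * tp_s) / lambda_e
  rise + tail
}

#' Analytic per-lesion peak dose for a noise-free synthetic dataset
#'
#' Independent oracle for end-to-end tests: the cumulated-activity map is
#' computed exactly (closed-form time integral of the rise/washout curve,
#' including the treatment extrapolation factors), convolved with the kernel,
#' and summarised with the same peak-dose rule as the pipeline. No scan-time
#' sampling or phase-wise integration is involved.
#'
#' @param dataset a `patient_dataset` from [generate_cohort()] (noise-free)
#' @param kernel `dose_voxel_kernel` of the target radionuclide
#' @param target `radiopharmaceutical` of the target plan (defaults to the
#'   delivered plan)
#' @param patient_mass_kg body mass for per-kg plans
#' @return data.frame with columns `lesion_id`, `peak_Gy`
#' @export
ground_truth_dose <- function(dataset, kernel, target = dataset$plan,
                              patient_mass_kg = NULL) {
  stopifnot(inherits(dataset, "patient_dataset"))
  config <- attr(dataset, "config")
  if (config$noise_cv > 0) {
    stop("ground_truth_dose requires a noise-free dataset (noise_cv = 0)",
         call. = FALSE)
  }
  if (is.null(patient_mass_kg)) patient_mass_kg <- config$patient_mass_kg
  delivered <- dataset$plan
  lambda_d <- effective_lambda_s(delivered)
  lambda_e <- effective_lambda_s(target)
  s <- (planned_activity(target, patient_mass_kg) *
          target$bone_uptake_fraction) /
    (planned_activity(delivered, patient_mass_kg) *
       delivered$bone_uptake_fraction)
  tp_s <- hours_to_seconds(config$time_to_peak_h)
  unit_integral <- tac_integral_exact(tp_s, lambda_d, lambda_e)

  # reconstruct the amplitude field from the mask and stored truth
  gd <- dim(dataset$mask$labels)
  a <- array(0, dim = gd)
  for (k in dataset$truth$lesion_id) {
    a[dataset$mask$labels == k] <- dataset$truth$amplitude_MBq[k]
  }
  if (dataset$background_amplitude_MBq > 0) {
    a[dataset$mask$labels == 0L] <- dataset$background_amplitude_MBq
  }
  cum <- cumulated_activity_map(a * s * unit_integral, config$voxel_size_mm,
                                provenance = list(plan_id = target$name,
                                                  method = "analytic"))
  dose <- convolve_dose(cum, kernel, method = "fft")
  data.frame(lesion_id = dataset$truth$lesion_id,
             peak_Gy = vapply(dataset$truth$lesion_id, function(k) {
               peak_dose(dose, dataset$mask, k)
             }, numeric(1)))
}
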