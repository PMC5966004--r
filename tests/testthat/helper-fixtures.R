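# shared fixtures: tiny cohorts and kernels kept small so the suite runs fast

tiny_cohort_config <- function(seed = 1L, noise_cv = 0, time_to_peak_h = 4,
                               schedule_h = c(1, 4, 24, 48, 72),
                               n_patients = 2L, grid = 36L,
                               lesions_mean = 4) {
  synthetic_cohort_config(
    n_patients = n_patients,
    grid_dim = rep(as.integer(grid), 3),
    lesions_per_patient_mean = lesions_mean,
    lesions_per_patient_range = c(1L, 10L),
    semi_axes_range_vox = c(2, 3.5),
    time_to_peak_h = time_to_peak_h,
    noise_cv = noise_cv,
    schedule_h = schedule_h,
    seed = seed)
}

small_kernels <- function(size = 9L, voxel_size_mm = 4.67) {
  default_kernels(size = size, voxel_size_mm = voxel_size_mm)
}

# brute-force convolution oracle: explicit sum over source voxels,
# independent of the engine's shift-and-add / FFT code paths
brute_force_convolve <- function(x, k) {
  nd <- dim(x); kd <- dim(k); half <- (kd - 1L) %/% 2L
  out <- array(0, dim = nd)
  src <- which(x != 0, arr.ind = TRUE)
  for (ti in seq_len(nd[1])) for (tj in seq_len(nd[2])) for (tk in seq_len(nd[3])) {
    acc <- 0
    for (s in seq_len(nrow(src))) {
      off <- c(ti, tj, tk) - src[s, ] + half + 1L
      if (all(off >= 1L) && all(off <= kd)) {
        acc <- acc + x[src[s, 1], src[s, 2], src[s, 3]] *
          k[off[1], off[2], off[3]]
      }
    }
    out[ti, tj, tk] <- acc
  }
  out
}
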