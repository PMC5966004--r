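#' Cumulated activity from per-voxel time-activity curves
#'
#' Cumulated activity (MBq.s) is the time integral of a voxel's
#' activity; it is the source term for voxel dosimetry. Integration between
#' scan time points is phase-wise: trapezoidal where the activity is
#' non-decreasing (uptake), monoexponential through the two samples where it
#' decreases (washout). The interval before the first scan and the tail beyond
#' the last are not observed and are handled by configurable rules.
#'
#' @name cumulation
NULL

#' Integrate one phase between two scan samples
#'
#' Non-decreasing activity (A2 >= A1): trapezoid, (A1 + A2)/2 * dt.
#' Decreasing activity: a monoexponential through both points,
#' integral (A1 - A2)/lambda with lambda = log(A1/A2)/dt. A2 = 0 falls back to
#' the trapezoid, the continuous limit where the exponential fit is undefined.
#'
#' @param t1_h,t2_h phase boundaries in hours, t2 > t1
#' @param A1,A2 activities at the boundaries, MBq (>= 0); may be arrays of a
#'   common shape for vectorised per-voxel use
#' @return integral in MBq.s, same shape as `A1`
#' @export
integrate_phase <- function(t1_h, t2_h, A1, A2) {
  if (t2_h <= t1_h) {
    stop("ordering error: t2 must exceed t1", call. = FALSE)
  }
  if (any(A1 < 0) || any(A2 < 0)) {
    stop("validation error: negative activities", call. = FALSE)
  }
  dt_s <- hours_to_seconds(t2_h - t1_h)
  out <- (A1 + A2) / 2 * dt_s # trapezoid branch (non-decreasing and A2 = 0)
  dec <- which(A2 < A1 & A2 > 0)
  if (length(dec)) {
    out[dec] <- (A1[dec] - A2[dec]) * dt_s / log(A1[dec] / A2[dec])
  }
  out
}

#' Integral from administration to the first scan
#'
#' The uptake phase before the first scan is unobserved. The default
#' `zero_start` rule assumes zero activity at administration and a linear rise
#' to the first sample (trapezoid from (0, 0)), matching the
#' trapezoid-for-increase convention; the `flat` rule holds the first sample
#' constant back to time zero and gives exactly twice the default.
#'
#' @param t_first_h time of the first scan, hours (> 0)
#' @param A_first activity at the first scan, MBq (may be an array)
#' @param rule `"zero_start"` or `"flat"`
#' @return integral in MBq.s, same shape as `A_first`
#' @export
head_integral <- function(t_first_h, A_first, rule = c("zero_start", "flat")) {
  rule <- match.arg(rule)
  check_positive(t_first_h, "t_first_h")
  t_s <- hours_to_seconds(t_first_h)
  switch(rule,
         zero_start = A_first / 2 * t_s,
         flat = A_first * t_s)
}

#' Analytic tail integral beyond the last scan
#'
#' Assumes monoexponential washout at rate `lambda_tail` from the last sample:
#' integral A_last / lambda_tail.
#'
#' @param A_last activity at the last scan, MBq (may be an array)
#' @param lambda_tail_per_s washout rate in s^-1 (> 0); may be an array
#'   matching `A_last`
#' @return integral in MBq.s
#' @export
tail_integral <- function(A_last, lambda_tail_per_s) {
  if (any(lambda_tail_per_s <= 0) || anyNA(lambda_tail_per_s)) {
    stop("invalid parameter: 'lambda_tail_per_s' must be > 0", call. = FALSE)
  }
  A_last / lambda_tail_per_s
}

#' Construct a cumulated-activity map
#' @param values 3D array, MBq.s per voxel, all >= 0
#' @param voxel_size_mm isotropic voxel pitch in mm
#' @param provenance list recording plan identifier and integration settings
#' @return an object of class `cumulated_activity_map`
#' @export
cumulated_activity_map <- function(values, voxel_size_mm, provenance = list()) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (any(values < 0)) {
    stop("validation error: cumulated activity must be >= 0", call. = FALSE)
  }
  check_positive(voxel_size_mm, "voxel_size_mm")
  structure(list(values = values, voxel_size_mm = voxel_size_mm,
                 provenance = provenance),
            class = "cumulated_activity_map")
}

#' Integrate a scan series into a cumulated-activity map
#'
#' Per voxel: head integral + phase-wise trapezoid/exponential integrals +
#' analytic tail. The tail rate is chosen per the `tail_rule` preference:
#' `"fit"` uses the per-voxel rate of the final phase where that phase is
#' decreasing, falling back to `lambda_fallback_per_s` elsewhere;
#' `"effective"`/`"physical"` use `lambda_fallback_per_s` everywhere (pass the
#' plan's effective or the nuclide's physical decay constant). The rule
#' actually applied is recorded in the map's provenance.
#'
#' @param series a `scan_series`
#' @param lambda_fallback_per_s fallback washout rate, s^-1 (the plan's
#'   effective decay constant in typical use)
#' @param head_rule see [head_integral()]
#' @param tail_rule `"fit"`, `"effective"` or `"physical"`
#' @param min_activity_MBq voxels whose peak sampled activity is below this
#'   threshold are skipped (set to 0)
#' @param plan_id identifier recorded in provenance
#' @return a `cumulated_activity_map` (MBq.s)
#' @export
integrate_series <- function(series, lambda_fallback_per_s,
                             head_rule = c("zero_start", "flat"),
                             tail_rule = c("fit", "effective", "physical"),
                             min_activity_MBq = 0,
                             plan_id = "unspecified") {
  stopifnot(inherits(series, "scan_series"))
  head_rule <- match.arg(head_rule)
  tail_rule <- match.arg(tail_rule)
  check_positive(lambda_fallback_per_s, "lambda_fallback_per_s")
  n <- length(series$times_h)
  dims <- dim(series$maps[[1]])

  acc <- head_integral(series$times_h[1], series$maps[[1]], head_rule)
  for (i in seq_len(n - 1L)) {
    acc <- acc + integrate_phase(series$times_h[i], series$times_h[i + 1L],
                                 series$maps[[i]], series$maps[[i + 1L]])
  }

  A_last <- series$maps[[n]]
  lambda_tail <- array(lambda_fallback_per_s, dim = dims)
  if (tail_rule == "fit") {
    A_prev <- series$maps[[n - 1L]]
    dt_s <- hours_to_seconds(series$times_h[n] - series$times_h[n - 1L])
    fit_ok <- which(A_last > 0 & A_prev > A_last)
    if (length(fit_ok)) {
      lambda_tail[fit_ok] <- log(A_prev[fit_ok] / A_last[fit_ok]) / dt_s
    }
  }
  tail <- array(0, dim = dims)
  nz <- which(A_last > 0)
  if (length(nz)) tail[nz] <- A_last[nz] / lambda_tail[nz]
  acc <- acc + tail

  if (min_activity_MBq > 0) {
    peak <- Reduce(pmax, series$maps)
    acc[peak < min_activity_MBq] <- 0
  }

  cumulated_activity_map(
    acc, series$voxel_size_mm,
    provenance = list(plan_id = plan_id,
                      patient_id = series$patient_id,
                      head_rule = head_rule,
                      tail_rule = tail_rule,
                      lambda_fallback_per_s = lambda_fallback_per_s,
                      min_activity_MBq = min_activity_MBq))
}
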