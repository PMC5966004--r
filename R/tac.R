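#' Per-voxel time-activity data and treatment extrapolation
#'
#' A `scan_series` holds co-registered sequential 3D activity maps (MBq per
#' voxel) at strictly increasing times post-administration: the per-voxel
#' time-activity curves of the delivered treatment. Extrapolation converts
#' them to the curves that an alternative radiopharmaceutical would have
#' produced, given its administered activity, effective decay constant and
#' skeletal uptake.
#'
#' @name tac
NULL

#' Construct a scan series
#'
#' @param times_h scan times in hours post-administration, strictly
#'   increasing, first time > 0, length >= 2
#' @param maps list of 3D numeric arrays (one per time), MBq per voxel,
#'   all the same shape, all values >= 0
#' @param voxel_size_mm isotropic voxel pitch in mm
#' @param patient_id identifier
#' @return an object of class `scan_series`
#' @export
scan_series <- function(times_h, maps, voxel_size_mm, patient_id = "patient") {
  stopifnot(is.numeric(times_h), length(times_h) >= 2L,
            is.list(maps), length(maps) == length(times_h))
  if (any(diff(times_h) <= 0) || times_h[1] <= 0) {
    stop("scan times must be strictly increasing with first time > 0",
         call. = FALSE)
  }
  dims <- dim(maps[[1]])
  if (is.null(dims) || length(dims) != 3L) {
    stop("each activity map must be a 3D array", call. = FALSE)
  }
  for (i in seq_along(maps)) {
    if (!identical(dim(maps[[i]]), dims)) {
      stop("all activity maps must share the same shape", call. = FALSE)
    }
    if (any(maps[[i]] < 0)) {
      stop("validation error: negative activities in map ", i, call. = FALSE)
    }
  }
  check_positive(voxel_size_mm, "voxel_size_mm")
  structure(list(times_h = as.numeric(times_h), maps = maps,
                 voxel_size_mm = voxel_size_mm,
                 patient_id = as.character(patient_id)),
            class = "scan_series")
}

#' @export
print.scan_series <- function(x, ...) {
  cat(sprintf(
    "<scan_series> patient %s: %d scans at %s h, grid %s @ %.3g mm\n",
    x$patient_id, length(x$times_h),
    paste(signif(x$times_h, 4), collapse = "/"),
    paste(dim(x$maps[[1]]), collapse = "x"), x$voxel_size_mm))
  invisible(x)
}

#' Monoexponential activity samples
#'
#' A(t) = A0 * exp(-lambda_eff * t), the single-compartment washout curve
#' underpinning the extrapolation model.
#'
#' @param A0_MBq activity at time zero, MBq
#' @param lambda_per_s effective decay constant, s^-1 (> 0)
#' @param times_h sampling times in hours
#' @return numeric vector of activities in MBq
#' @export
sample_monoexponential <- function(A0_MBq, lambda_per_s, times_h) {
  check_positive(lambda_per_s, "lambda_per_s")
  stopifnot(is.numeric(A0_MBq), A0_MBq >= 0, is.numeric(times_h))
  A0_MBq * exp(-lambda_per_s * hours_to_seconds(times_h))
}

#' Extrapolate a scan series to an alternative radiopharmaceutical
#'
#' Per voxel and scan time, the extrapolated activity is
#' \deqn{A^E(t) = \frac{A_0^E}{A_0^D} A^D(t)
#'   \exp[(\lambda_{eff}^D - \lambda_{eff}^E) t] \cdot \frac{U^E}{U^D}}
#' where D and E are the delivered and extrapolated plans, A0 the administered
#' activities, lambda_eff the effective decay constants and U the skeletal
#' uptake fractions. The uptake ratio is a uniform multiplicative factor: the
#' measured images already embody the delivered uptake, so rescaling converts
#' it to the target's. Extrapolation applies to every voxel including
#' background; lesion restriction happens later via masks.
#'
#' @param series a `scan_series` of the delivered treatment
#' @param delivered `radiopharmaceutical` of the delivered plan
#' @param target `radiopharmaceutical` of the target plan
#' @param patient_mass_kg body mass, needed when either plan is per-kg
#' @return a `scan_series` at the same times, for the target plan
#' @export
extrapolate_series <- function(series, delivered, target,
                               patient_mass_kg = NULL) {
  stopifnot(inherits(series, "scan_series"),
            inherits(delivered, "radiopharmaceutical"),
            inherits(target, "radiopharmaceutical"))
  a0_ratio <- planned_activity(target, patient_mass_kg) /
    planned_activity(delivered, patient_mass_kg)
  uptake_ratio <- target$bone_uptake_fraction / delivered$bone_uptake_fraction
  lambda_d <- effective_lambda_s(delivered)
  lambda_e <- effective_lambda_s(target)
  t_s <- hours_to_seconds(series$times_h)
  scale <- a0_ratio * uptake_ratio * exp((lambda_d - lambda_e) * t_s)
  maps <- lapply(seq_along(series$maps),
                 function(i) series$maps[[i]] * scale[i])
  scan_series(series$times_h, maps, series$voxel_size_mm, series$patient_id)
}

#' Read a scan series from a manifest
#'
#' The manifest is a JSON file with fields `patient_id`, `voxel_size_mm` and
#' an array `scans` of `{time_h, path}` entries; each path is a NIfTI volume
#' of per-voxel activities in MBq, relative to the manifest's directory.
#'
#' @param manifest_path path to the JSON manifest
#' @return a `scan_series`
#' @export
read_scan_series <- function(manifest_path) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  base <- dirname(manifest_path)
  times <- vapply(m$scans, function(s) as.numeric(s$time_h), numeric(1))
  ord <- order(times)
  maps <- lapply(m$scans[ord], function(s) {
    v <- RNifti::readNifti(file.path(base, s$path))
    array(as.numeric(v), dim = dim(v))
  })
  scan_series(times[ord], maps, m$voxel_size_mm, m$patient_id)
}

#' Write a scan series as NIfTI volumes plus a JSON manifest
#'
#' @param series a `scan_series`
#' @param dir output directory (created if missing)
#' @param prefix filename prefix for the volumes
#' @return the manifest path, invisibly
#' @export
write_scan_series <- function(series, dir, prefix = series$patient_id) {
  stopifnot(inherits(series, "scan_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pd <- c(series$voxel_size_mm, series$voxel_size_mm, series$voxel_size_mm)
  scans <- lapply(seq_along(series$times_h), function(i) {
    fname <- sprintf("%s_t%03d.nii", prefix, i)
    img <- RNifti::asNifti(series$maps[[i]], internal = FALSE)
    RNifti::pixdim(img) <- pd
    RNifti::writeNifti(img, file.path(dir, fname))
    list(time_h = series$times_h[i], path = fname)
  })
  manifest <- list(patient_id = series$patient_id,
                   voxel_size_mm = series$voxel_size_mm,
                   scans = scans)
  manifest_path <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest_path)
}
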