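#' Cohort disk round-trip
#'
#' A cohort directory holds one subdirectory per patient with the scan-series
#' NIfTI volumes, the series manifest and the lesion mask, plus a top-level
#' `cohort.json` index. Written cohorts are indistinguishable from real inputs
#' to the downstream stages.
#'
#' @name cohort_io
NULL

#' Write a cohort to a directory
#' @param cohort list of datasets with elements `series` and `mask`
#' @param dir destination directory
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  index <- lapply(cohort, function(d) {
    pid <- d$series$patient_id
    pdir <- file.path(dir, pid)
    manifest <- write_scan_series(d$series, pdir)
    mask_path <- file.path(pdir, paste0(pid, "_mask.nii"))
    write_lesion_mask(d$mask, mask_path)
    list(patient_id = pid,
         manifest = file.path(pid, basename(manifest)),
         mask = file.path(pid, basename(mask_path)))
  })
  jsonlite::write_json(list(patients = index), file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort from a directory written by [write_cohort()]
#' @param dir cohort directory containing `cohort.json`
#' @return list of datasets with elements `series` and `mask`
#' @export
read_cohort <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "cohort.json"),
                             simplifyVector = FALSE)
  lapply(idx$patients, function(p) {
    series <- read_scan_series(file.path(dir, p$manifest))
    mask <- read_lesion_mask(file.path(dir, p$mask),
                             patient_id = p$patient_id)
    list(series = series, mask = mask)
  })
}
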