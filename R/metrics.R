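#' Lesion dose statistics and cohort summaries
#'
#' Per-lesion peak absorbed doses (the lesion maximum voxel averaged with its
#' first nearest neighbours, reducing partial-volume sensitivity), cohort dose
#' profiles with log-normal fits, cumulative dose-volume histograms over the
#' pooled disease volume, D50, and treatment comparison tables.
#'
#' @name lesion_metrics
NULL

#' Construct a lesion mask
#'
#' @param labels 3D integer array: 0 = background, k > 0 = lesion k; each
#'   lesion must have at least one voxel
#' @param voxel_size_mm isotropic voxel pitch in mm
#' @param patient_id identifier
#' @return an object of class `lesion_mask`
#' @export
lesion_mask <- function(labels, voxel_size_mm, patient_id = "patient") {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  if (any(labels < 0) || any(labels != round(labels))) {
    stop("labels must be non-negative integers", call. = FALSE)
  }
  check_positive(voxel_size_mm, "voxel_size_mm")
  structure(list(labels = labels, voxel_size_mm = voxel_size_mm,
                 patient_id = as.character(patient_id)),
            class = "lesion_mask")
}

#' Lesion ids present in a mask
#' @param mask a `lesion_mask`
#' @return sorted integer vector of positive labels
#' @export
lesion_ids <- function(mask) {
  u <- sort(unique(as.integer(mask$labels)))
  u[u > 0L]
}

#' Voxel volume in ml for a given voxel pitch
#' @param voxel_size_mm isotropic voxel pitch in mm
#' @return volume of one voxel in ml
#' @export
voxel_volume_ml <- function(voxel_size_mm) voxel_size_mm^3 / 1000

#' Peak absorbed dose of a lesion
#'
#' Locates the maximum-dose voxel within the lesion and averages it with its
#' first nearest neighbours. `"face6"` (default) uses the 6 face-adjacent
#' voxels; `"full26"` the full 26-neighbourhood. Neighbours outside the lesion
#' but inside the volume are included in the average; neighbours outside the
#' volume are dropped. Ties for the maximum resolve to the first voxel in
#' column-major order.
#'
#' @param dose an `absorbed_dose_map`
#' @param mask a `lesion_mask` of the same shape
#' @param lesion_id positive integer label
#' @param neighbourhood `"face6"` or `"full26"`
#' @return peak dose in Gy
#' @export
peak_dose <- function(dose, mask, lesion_id,
                      neighbourhood = c("face6", "full26")) {
  stopifnot(inherits(dose, "absorbed_dose_map"),
            inherits(mask, "lesion_mask"),
            identical(dim(dose$values), dim(mask$labels)))
  neighbourhood <- match.arg(neighbourhood)
  idx <- which(mask$labels == lesion_id)
  if (length(idx) == 0L) {
    stop("missing lesion: no voxels labelled ", lesion_id, call. = FALSE)
  }
  dmax_idx <- idx[which.max(dose$values[idx])]
  nd <- dim(dose$values)
  pos <- arrayInd(dmax_idx, nd)
  offs <- if (neighbourhood == "face6") {
    rbind(c(0, 0, 0),
          c(-1, 0, 0), c(1, 0, 0),
          c(0, -1, 0), c(0, 1, 0),
          c(0, 0, -1), c(0, 0, 1))
  } else {
    as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  }
  nb <- sweep(offs, 2, as.integer(pos), `+`)
  inside <- nb[, 1] >= 1 & nb[, 1] <= nd[1] &
    nb[, 2] >= 1 & nb[, 2] <= nd[2] &
    nb[, 3] >= 1 & nb[, 3] <= nd[3]
  nb <- nb[inside, , drop = FALSE]
  mean(dose$values[nb])
}

#' Per-lesion dose records for one patient
#'
#' @param dose an `absorbed_dose_map`
#' @param mask a `lesion_mask` of the same shape
#' @param neighbourhood passed to [peak_dose()]
#' @return data.frame with columns `patient_id`, `lesion_id`, `volume_ml`,
#'   `peak_Gy`, `mean_Gy`
#' @export
lesion_dose_table <- function(dose, mask, neighbourhood = "face6") {
  ids <- lesion_ids(mask)
  vvol <- voxel_volume_ml(mask$voxel_size_mm)
  rows <- lapply(ids, function(k) {
    idx <- which(mask$labels == k)
    data.frame(patient_id = mask$patient_id,
               lesion_id = k,
               volume_ml = length(idx) * vvol,
               peak_Gy = peak_dose(dose, mask, k, neighbourhood),
               mean_Gy = mean(dose$values[idx]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Maximum-likelihood log-normal fit
#'
#' Fits log-normal parameters to positive doses by maximum likelihood on the
#' logs: `mu` is the mean and `sigma` the population (1/n) standard deviation
#' of `log(dose)`.
#'
#' @param doses_Gy numeric vector of doses, all > 0, length >= 2
#' @return list with `mu`, `sigma` (log-Gy scale), `n`
#' @export
fit_lognormal <- function(doses_Gy) {
  if (length(doses_Gy) < 2L) {
    stop("validation error: need at least 2 doses to fit", call. = FALSE)
  }
  if (any(doses_Gy <= 0) || anyNA(doses_Gy)) {
    stop("validation error: all doses must be positive", call. = FALSE)
  }
  lg <- log(doses_Gy)
  mu <- mean(lg)
  sigma <- sqrt(mean((lg - mu)^2))
  list(mu = mu, sigma = sigma, n = length(doses_Gy))
}

#' Cohort dose profile
#'
#' Pools per-lesion peak doses across patients and fits a log-normal
#' distribution (when at least two positive doses are available).
#'
#' @param records data.frame as from [lesion_dose_table()], rows from one or
#'   more patients
#' @param dose_column column holding the per-lesion dose (default `peak_Gy`)
#' @return list of class `cohort_dose_profile`: `records`, `dose_column`,
#'   `lognormal` (fit or NULL), `median_Gy`, `min_Gy`, `max_Gy`
#' @export
cohort_dose_profile <- function(records, dose_column = "peak_Gy") {
  stopifnot(is.data.frame(records), dose_column %in% names(records),
            nrow(records) >= 1L)
  d <- records[[dose_column]]
  fit <- if (sum(d > 0) >= 2L) fit_lognormal(d[d > 0]) else NULL
  structure(list(records = records, dose_column = dose_column,
                 lognormal = fit,
                 median_Gy = stats::median(d),
                 min_Gy = min(d), max_Gy = max(d)),
            class = "cohort_dose_profile")
}

#' @export
print.cohort_dose_profile <- function(x, ...) {
  cat(sprintf(
    "<cohort_dose_profile> %d lesions: median %.3g [%.3g-%.3g] Gy",
    nrow(x$records), x$median_Gy, x$min_Gy, x$max_Gy))
  if (!is.null(x$lognormal)) {
    cat(sprintf("; log-normal mu %.3g, sigma %.3g", x$lognormal$mu,
                x$lognormal$sigma))
  }
  cat("\n")
  invisible(x)
}

#' Cumulative dose-volume histogram over the pooled disease volume
#'
#' Pools voxel-level doses from every lesion voxel across the cohort, weighted
#' by voxel volume. The covered fraction at dose D is the disease volume
#' receiving at least D divided by the total disease volume (the sum of all
#' patients' lesion volumes).
#'
#' @param doses list of `absorbed_dose_map`, one per patient
#' @param masks list of `lesion_mask`, parallel to `doses`
#' @param n_grid number of evaluation points for the tabulated curve
#' @return object of class `cdvh`: `dose_Gy` grid, `covered_fraction`,
#'   `total_volume_ml`, plus the pooled voxel doses/volumes used
#' @export
build_cdvh <- function(doses, masks, n_grid = 512L) {
  stopifnot(is.list(doses), is.list(masks), length(doses) == length(masks),
            length(doses) >= 1L)
  pooled_dose <- numeric(0)
  pooled_vol <- numeric(0)
  for (i in seq_along(doses)) {
    stopifnot(inherits(doses[[i]], "absorbed_dose_map"),
              inherits(masks[[i]], "lesion_mask"),
              identical(dim(doses[[i]]$values), dim(masks[[i]]$labels)))
    idx <- which(masks[[i]]$labels > 0L)
    if (length(idx)) {
      pooled_dose <- c(pooled_dose, doses[[i]]$values[idx])
      pooled_vol <- c(pooled_vol,
                      rep(voxel_volume_ml(masks[[i]]$voxel_size_mm),
                          length(idx)))
    }
  }
  if (length(pooled_dose) == 0L) {
    stop("empty cohort: no lesion voxels found", call. = FALSE)
  }
  total <- sum(pooled_vol)
  ord <- order(pooled_dose, decreasing = TRUE)
  pooled_dose <- pooled_dose[ord]
  pooled_vol <- pooled_vol[ord]
  grid <- seq(0, max(pooled_dose), length.out = n_grid)
  # volume with dose >= g, via cumulative volumes on the descending sort
  cumvol <- cumsum(pooled_vol)
  n_ge <- length(pooled_dose) -
    findInterval(grid, rev(pooled_dose), left.open = TRUE)
  covered <- ifelse(n_ge > 0, cumvol[pmax(n_ge, 1L)], 0) / total
  covered[n_ge == 0] <- 0
  structure(list(dose_Gy = grid, covered_fraction = covered,
                 total_volume_ml = total,
                 voxel_dose_Gy = pooled_dose, voxel_volume_ml = pooled_vol),
            class = "cdvh")
}

#' Covered fraction of a cDVH at arbitrary doses
#' @param cdvh a `cdvh`
#' @param dose_Gy doses at which to evaluate
#' @return fraction of the total disease volume receiving >= each dose
#' @export
covered_fraction <- function(cdvh, dose_Gy) {
  stopifnot(inherits(cdvh, "cdvh"))
  cumvol <- cumsum(cdvh$voxel_volume_ml)
  n_ge <- length(cdvh$voxel_dose_Gy) -
    findInterval(dose_Gy, rev(cdvh$voxel_dose_Gy), left.open = TRUE)
  out <- ifelse(n_ge > 0, cumvol[pmax(n_ge, 1L)], 0) / cdvh$total_volume_ml
  out[n_ge == 0] <- 0
  out
}

#' D50: minimum dose covering half the disease volume
#'
#' The largest dose D for which at least 50% of the total disease volume
#' receives >= D: the upper median of the pooled, volume-weighted voxel dose
#' distribution (right-continuous step convention; interpolation is used only
#' for plotting).
#'
#' @param cdvh a `cdvh`
#' @param fraction coverage fraction (default 0.5)
#' @return dose in Gy
#' @export
d50 <- function(cdvh, fraction = 0.5) {
  stopifnot(inherits(cdvh, "cdvh"), fraction > 0, fraction <= 1)
  cumvol <- cumsum(cdvh$voxel_volume_ml)
  k <- which(cumvol >= fraction * cdvh$total_volume_ml - 1e-12)[1]
  cdvh$voxel_dose_Gy[k]
}

#' Percent difference of a target median from the delivered median
#' @param median_target,median_delivered medians in Gy
#' @return 100 * (median_target / median_delivered - 1), unrounded
#' @export
percent_difference <- function(median_target, median_delivered) {
  check_positive(median_delivered, "median_delivered")
  100 * (median_target / median_delivered - 1)
}

#' Compare delivered and extrapolated treatment plans
#'
#' Builds the standard report: per plan the median [min-max] peak lesion dose,
#' the percent difference of the median from the delivered plan (computed from
#' unrounded medians, then rounded to the nearest integer), and D50. All plans
#' must cover the same lesion set.
#'
#' @param profiles named list of `cohort_dose_profile`, one per plan
#' @param delivered name of the delivered plan within `profiles`
#' @param cdvhs optional named list of `cdvh` parallel to `profiles`; when
#'   supplied a `D50_Gy` column is added
#' @return data.frame with columns `plan`, `median_Gy`, `min_Gy`, `max_Gy`,
#'   `pct_diff_unrounded`, `pct_diff`, and optionally `D50_Gy`
#' @export
compare_treatments <- function(profiles, delivered, cdvhs = NULL) {
  stopifnot(is.list(profiles), delivered %in% names(profiles))
  key <- function(p) {
    r <- p$records
    sort(paste(r$patient_id, r$lesion_id, sep = "/"))
  }
  ref_key <- key(profiles[[delivered]])
  for (nm in names(profiles)) {
    if (!identical(key(profiles[[nm]]), ref_key)) {
      stop("mismatched lesion sets: plan '", nm,
           "' does not cover the delivered plan's lesions", call. = FALSE)
    }
  }
  med_d <- profiles[[delivered]]$median_Gy
  out <- do.call(rbind, lapply(names(profiles), function(nm) {
    p <- profiles[[nm]]
    pd <- percent_difference(p$median_Gy, med_d)
    data.frame(plan = nm, median_Gy = p$median_Gy,
               min_Gy = p$min_Gy, max_Gy = p$max_Gy,
               pct_diff_unrounded = pd,
               pct_diff = round(pd),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(cdvhs)) {
    stopifnot(all(names(profiles) %in% names(cdvhs)))
    out$D50_Gy <- vapply(out$plan, function(nm) d50(cdvhs[[nm]]), numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Read a lesion mask from a NIfTI label volume
#' @param path NIfTI path
#' @param patient_id identifier
#' @return a `lesion_mask`
#' @export
read_lesion_mask <- function(path, patient_id = "patient") {
  v <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(v)[1]
  lesion_mask(array(as.integer(round(as.numeric(v))), dim = dim(v)),
              voxel_size_mm = vox, patient_id = patient_id)
}

#' Write a lesion mask as a NIfTI label volume
#' @param mask a `lesion_mask`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_lesion_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lesion_mask"))
  img <- RNifti::asNifti(mask$labels + 0L, internal = FALSE)
  RNifti::pixdim(img) <- rep(mask$voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}
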