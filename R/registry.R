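#' Radiopharmaceutical registry and half-life algebra
#'
#' A registry entry couples the physics of a radionuclide (physical half-life)
#' with the lesion biokinetics of the labelled pharmaceutical (biological or
#' effective half-life, skeletal uptake fraction) and a typical treatment plan
#' (administered activity, absolute MBq or MBq per kg of body mass).
#'
#' Decay constants add: lambda_eff = lambda_phys + lambda_bio, so the effective
#' half-life never exceeds the physical one (equality only for infinite
#' biological half-life, i.e. no biological clearance).
#'
#' @name registry
NULL

#' Effective decay constant from physical and biological half-lives
#'
#' Physical decay and biological clearance are independent first-order losses,
#' so their decay constants add.
#'
#' @param physical_half_life_d physical half-life in days (> 0, finite)
#' @param biological_half_life_d biological half-life in days (> 0, may be
#'   `Inf` for no biological clearance)
#' @return effective decay constant in day^-1; the effective half-life is
#'   `log(2)` divided by the returned value
#' @examples
#' log(2) / effective_decay_constant(50.563, 70) # ~29.4 d
#' @export
effective_decay_constant <- function(physical_half_life_d, biological_half_life_d) {
  check_positive(physical_half_life_d, "physical_half_life_d")
  check_positive(biological_half_life_d, "biological_half_life_d", allow_inf = TRUE)
  log(2) / physical_half_life_d + log(2) / biological_half_life_d
}

#' Effective half-life (days) from physical and biological half-lives
#' @inheritParams effective_decay_constant
#' @return effective half-life in days
#' @export
effective_half_life <- function(physical_half_life_d, biological_half_life_d) {
  log(2) / effective_decay_constant(physical_half_life_d, biological_half_life_d)
}

#' Biological half-life from physical and effective half-lives
#'
#' Inverts the sum-of-decay-constants relation:
#' 1/Tbio = 1/Teff - 1/Tphys.
#'
#' @param physical_half_life_d physical half-life in days (> 0)
#' @param effective_half_life_d effective half-life in days, 0 < Teff <= Tphys
#' @return biological half-life in days (`Inf` when Teff equals Tphys)
#' @export
biological_half_life_from_effective <- function(physical_half_life_d,
                                                effective_half_life_d) {
  check_positive(physical_half_life_d, "physical_half_life_d")
  check_positive(effective_half_life_d, "effective_half_life_d")
  if (effective_half_life_d > physical_half_life_d) {
    stop("invalid parameter: effective half-life exceeds physical half-life; ",
         "no finite biological half-life exists", call. = FALSE)
  }
  if (effective_half_life_d == physical_half_life_d) return(Inf)
  1 / (1 / effective_half_life_d - 1 / physical_half_life_d)
}

#' Construct a radiopharmaceutical registry entry
#'
#' Exactly one of `effective_half_life_d` and `biological_half_life_d` must be
#' supplied; the other is derived from the sum-of-decay-constants relation.
#'
#' @param name identifier, unique within a registry
#' @param physical_half_life_d physical half-life in days
#' @param effective_half_life_d lesion effective half-life in days (optional)
#' @param biological_half_life_d lesion biological half-life in days (optional;
#'   `Inf` means no biological clearance)
#' @param bone_uptake_fraction fraction of administered activity taken up by
#'   the skeleton/lesions, in (0, 1]
#' @param administered_activity_MBq absolute administered activity in MBq
#'   (mutually exclusive with the per-kg form)
#' @param administered_activity_MBq_per_kg administered activity per kg body
#'   mass
#' @return an object of class `radiopharmaceutical`
#' @export
radiopharmaceutical <- function(name,
                                physical_half_life_d,
                                effective_half_life_d = NULL,
                                biological_half_life_d = NULL,
                                bone_uptake_fraction,
                                administered_activity_MBq = NULL,
                                administered_activity_MBq_per_kg = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_positive(physical_half_life_d, "physical_half_life_d")
  if (is.null(effective_half_life_d) == is.null(biological_half_life_d)) {
    stop("supply exactly one of 'effective_half_life_d' and ",
         "'biological_half_life_d'", call. = FALSE)
  }
  if (is.null(effective_half_life_d)) {
    check_positive(biological_half_life_d, "biological_half_life_d",
                   allow_inf = TRUE)
    effective_half_life_d <- effective_half_life(physical_half_life_d,
                                                 biological_half_life_d)
  } else {
    check_positive(effective_half_life_d, "effective_half_life_d")
    biological_half_life_d <- biological_half_life_from_effective(
      physical_half_life_d, effective_half_life_d)
  }
  if (effective_half_life_d > physical_half_life_d + 1e-9) {
    stop("invalid parameter: effective half-life exceeds physical half-life",
         call. = FALSE)
  }
  check_positive(bone_uptake_fraction, "bone_uptake_fraction")
  if (bone_uptake_fraction > 1) {
    stop("invalid parameter: 'bone_uptake_fraction' must lie in (0, 1]",
         call. = FALSE)
  }
  if (is.null(administered_activity_MBq) ==
      is.null(administered_activity_MBq_per_kg)) {
    stop("supply exactly one of 'administered_activity_MBq' and ",
         "'administered_activity_MBq_per_kg'", call. = FALSE)
  }
  if (!is.null(administered_activity_MBq)) {
    check_positive(administered_activity_MBq, "administered_activity_MBq")
  } else {
    check_positive(administered_activity_MBq_per_kg,
                   "administered_activity_MBq_per_kg")
  }
  structure(
    list(name = name,
         physical_half_life_d = physical_half_life_d,
         effective_half_life_d = effective_half_life_d,
         biological_half_life_d = biological_half_life_d,
         bone_uptake_fraction = bone_uptake_fraction,
         administered_activity_MBq = administered_activity_MBq,
         administered_activity_MBq_per_kg = administered_activity_MBq_per_kg),
    class = "radiopharmaceutical")
}

#' @export
print.radiopharmaceutical <- function(x, ...) {
  act <- if (!is.null(x$administered_activity_MBq)) {
    sprintf("%g MBq", x$administered_activity_MBq)
  } else {
    sprintf("%g MBq/kg", x$administered_activity_MBq_per_kg)
  }
  cat(sprintf(
    "<radiopharmaceutical> %s\n  Tphys %.4g d | Teff %.4g d | Tbio %.4g d | uptake %.0f%% | %s\n",
    x$name, x$physical_half_life_d, x$effective_half_life_d,
    x$biological_half_life_d, 100 * x$bone_uptake_fraction, act))
  invisible(x)
}

#' Effective decay constant of a registry entry, in s^-1
#' @param rp a `radiopharmaceutical`
#' @return decay constant in s^-1
#' @export
effective_lambda_s <- function(rp) {
  stopifnot(inherits(rp, "radiopharmaceutical"))
  lambda_per_second(rp$effective_half_life_d)
}

#' Administered activity of a plan in MBq
#'
#' Absolute plans return the stated activity; per-kg plans require the patient
#' body mass.
#'
#' @param rp a `radiopharmaceutical`
#' @param patient_mass_kg body mass in kg; required for per-kg plans
#' @return administered activity in MBq
#' @export
planned_activity <- function(rp, patient_mass_kg = NULL) {
  stopifnot(inherits(rp, "radiopharmaceutical"))
  if (!is.null(rp$administered_activity_MBq)) {
    return(rp$administered_activity_MBq)
  }
  if (is.null(patient_mass_kg)) {
    stop("missing parameter: plan '", rp$name,
         "' is per-kg; 'patient_mass_kg' is required", call. = FALSE)
  }
  check_positive(patient_mass_kg, "patient_mass_kg")
  rp$administered_activity_MBq_per_kg * patient_mass_kg
}

#' Default registry of bone-seeking radiopharmaceuticals
#'
#' Seven radiopharmaceuticals used for bone pain palliation in metastatic
#' castration-resistant prostate cancer, with physical half-lives, lesion
#' effective half-lives, skeletal uptake (fraction of administered activity)
#' and typical administered activities. Percent uptakes are stored as
#' fractions.
#'
#' The delivered Re-186 HEDP plan's lesion kinetics are not as firmly
#' established as the others; its effective half-life and uptake default to
#' 2.7 d and 0.30 but can be overridden, and every pipeline report records the
#' values actually used.
#'
#' @param re186_effective_half_life_d lesion effective half-life of the
#'   delivered Re-186 HEDP plan, days
#' @param re186_bone_uptake_fraction skeletal uptake fraction of the delivered
#'   Re-186 HEDP plan
#' @param re186_administered_activity_MBq administered activity of the
#'   delivered Re-186 HEDP plan, MBq (cohort median 5020 MBq)
#' @return named list of `radiopharmaceutical` objects, class
#'   `radiopharm_registry`
#' @export
load_default_registry <- function(re186_effective_half_life_d = 2.7,
                                  re186_bone_uptake_fraction = 0.30,
                                  re186_administered_activity_MBq = 5020) {
  entries <- list(
    radiopharmaceutical("32P-Na3PO4", physical_half_life_d = 14.268,
                        effective_half_life_d = 13,
                        bone_uptake_fraction = 0.20,
                        administered_activity_MBq = 450),
    radiopharmaceutical("89Sr-dichloride", physical_half_life_d = 50.563,
                        effective_half_life_d = 29,
                        bone_uptake_fraction = 0.65,
                        administered_activity_MBq = 150),
    radiopharmaceutical("153Sm-EDTMP", physical_half_life_d = 1.9379,
                        effective_half_life_d = 1.6,
                        bone_uptake_fraction = 0.70,
                        administered_activity_MBq_per_kg = 37),
    radiopharmaceutical("166Ho-DOTMP", physical_half_life_d = 1.1177,
                        effective_half_life_d = 0.93,
                        bone_uptake_fraction = 0.30,
                        administered_activity_MBq = 1100),
    radiopharmaceutical("177Lu-EDTMP", physical_half_life_d = 6.647,
                        effective_half_life_d = 3.9,
                        bone_uptake_fraction = 0.60,
                        administered_activity_MBq_per_kg = 37),
    radiopharmaceutical("186Re-HEDP", physical_half_life_d = 3.7183,
                        effective_half_life_d = re186_effective_half_life_d,
                        bone_uptake_fraction = re186_bone_uptake_fraction,
                        administered_activity_MBq =
                          re186_administered_activity_MBq),
    radiopharmaceutical("188Re-HEDP", physical_half_life_d = 0.78500,
                        effective_half_life_d = 0.66,
                        bone_uptake_fraction = 0.30,
                        administered_activity_MBq = 3300)
  )
  names(entries) <- vapply(entries, `[[`, character(1), "name")
  structure(entries, class = "radiopharm_registry")
}

#' @export
print.radiopharm_registry <- function(x, ...) {
  cat(sprintf("<radiopharm_registry> %d entries\n", length(x)))
  for (rp in x) print(rp)
  invisible(x)
}

#' Read a registry from a JSON file
#'
#' The file is a JSON array of objects with keys `name`,
#' `physical_half_life_d`, one of `effective_half_life_d` /
#' `biological_half_life_d`, `bone_uptake_percent`, and one of
#' `administered_activity_MBq` / `administered_activity_MBq_per_kg`.
#' Percent uptakes are divided by 100 on load.
#'
#' @param path path to the JSON registry file
#' @return a `radiopharm_registry`
#' @export
read_registry <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- lapply(raw, function(e) {
    radiopharmaceutical(
      name = e[["name"]],
      physical_half_life_d = e[["physical_half_life_d"]],
      effective_half_life_d = e[["effective_half_life_d"]],
      biological_half_life_d =
        if (!is.null(e[["biological_half_life_d"]]) &&
            identical(e[["biological_half_life_d"]], "Inf")) Inf
        else e[["biological_half_life_d"]],
      bone_uptake_fraction = e[["bone_uptake_percent"]] / 100,
      administered_activity_MBq = e[["administered_activity_MBq"]],
      administered_activity_MBq_per_kg = e[["administered_activity_MBq_per_kg"]])
  })
  nm <- vapply(entries, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("registry names must be unique; duplicated: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  names(entries) <- nm
  structure(entries, class = "radiopharm_registry")
}

#' Write a registry to a JSON file
#' @param registry a `radiopharm_registry`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "radiopharm_registry"))
  out <- lapply(unname(registry), function(rp) {
    e <- list(name = rp$name,
              physical_half_life_d = rp$physical_half_life_d,
              effective_half_life_d = rp$effective_half_life_d,
              bone_uptake_percent = 100 * rp$bone_uptake_fraction)
    if (!is.null(rp$administered_activity_MBq)) {
      e$administered_activity_MBq <- rp$administered_activity_MBq
    } else {
      e$administered_activity_MBq_per_kg <- rp$administered_activity_MBq_per_kg
    }
    e
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
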