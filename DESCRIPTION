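Package: voxdose
Title: Voxel-Based Absorbed Dose Extrapolation for Bone-Seeking Radiopharmaceuticals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-level internal dosimetry pipeline for molecular radiotherapy
    of bone metastases. Extrapolates per-voxel time-activity curves measured for
    a delivered radiopharmaceutical to alternative radiopharmaceuticals using
    effective decay constants, administered activities and bone uptake fractions;
    integrates time-activity curves to cumulated activity with a phase-wise
    trapezoid/monoexponential rule; convolves cumulated-activity maps with
    dose-voxel kernels (voxel S-values) to obtain absorbed-dose maps; and
    summarises lesion absorbed doses as peak doses, log-normal cohort profiles,
    cumulative dose-volume histograms and D50. Includes a seeded synthetic-cohort
    generator producing SPECT-like activity map series and lesion masks so the
    full pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
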