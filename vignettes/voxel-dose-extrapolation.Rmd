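---
title: "Methods: voxel-level absorbed-dose extrapolation between bone-seeking radiopharmaceuticals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-level absorbed-dose extrapolation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the model implemented by `voxdose`, the parameters it
ships with, the numerical choices that were open to interpretation and how
they were resolved, and the limits of what the synthetic cohort generator
emulates. All code chunks are illustrative and not evaluated at build time.

## 1. Setting

A patient receives a bone-seeking radiopharmaceutical (the *delivered* plan,
e.g. ¹⁸⁶Re-HEDP) and is imaged quantitatively at several time points, giving a
per-voxel time-activity curve (TAC) A_D(t) in MBq on a regular 3-D grid.
Because the bisphosphonate/phosphonate chelators used by these agents share a
common targeting mechanism (adsorption to bone mineral at sites of active
turnover), the spatial uptake pattern can be assumed agent-independent to
first order. Under that assumption, the TACs an *alternative* agent E would
have produced in the same patient are predictable from the measured ones, and
with them the full 3-D absorbed-dose distribution — enabling an in-silico
head-to-head comparison of treatments that has never been performed
clinically.

## 2. Radiopharmaceutical model

Each registry entry (`load_default_registry()`) carries:

* physical half-life T_phys (days),
* effective half-life T_eff **or** biological half-life T_bio — the package
  stores both, related through addition of decay constants,
  λ_eff = λ_phys + λ_bio, so T_eff ≤ T_phys always holds;
* bone uptake fraction U ∈ (0, 1] — the fraction of the injected activity
  retained in the skeleton;
* planned administered activity A0, absolute (MBq) or per body mass (MBq/kg).

The seven default entries cover ³²P-Na₃PO₄, ⁸⁹Sr-dichloride, ¹⁵³Sm-EDTMP,
¹⁶⁶Ho-DOTMP, ¹⁷⁷Lu-EDTMP, ¹⁸⁶Re-HEDP and ¹⁸⁸Re-HEDP. Where the literature
gives a range rather than a value (the ⁸⁹Sr biological half-life, reported
between roughly 50 and 90 days in skeletal retention studies), the registry
uses the midpoint; the resulting effective half-life rounds to 29 days. The
delivered-plan kinetics (¹⁸⁶Re-HEDP effective half-life, uptake fraction and
administered activity) are constructor arguments so sensitivity analyses do
not require editing the package.

## 3. TAC extrapolation

The delivered voxel TAC is mapped to target agent E as

    A_E(t) = A_D(t) · (A0_E / A0_D) · (U_E / U_D) · exp[(λ_D − λ_E) t].

The exponential factor swaps the delivered effective decay rate for the
target's while preserving the *biological* shape of the curve; the two ratios
rescale for administered activity and skeletal uptake. The operation is an
exact involution (D→E→D is the identity), which the test suite checks to
1e-10.

## 4. Cumulated activity

The time integral Ã (MBq·s) of each voxel's TAC is computed phase by phase
over the scan schedule:

* **between scans** — trapezoid where activity is non-decreasing or falls to
  exactly zero; otherwise a monoexponential through the two samples,
  integrated analytically as (A₁ − A₂)/λ with λ = log(A₁/A₂)/Δt. This follows
  the standard practice of trapezoidal integration during uptake and
  exponential integration during washout.
* **head** (administration to first scan) — `"zero_start"` (default):
  trapezoid from (0, 0), appropriate when uptake genuinely starts from zero;
  or `"flat"`: hold the first sample constant, appropriate when the first
  scan already sits on the washout curve.
* **tail** (after the last scan) — analytic monoexponential A_last/λ, with λ
  taken per voxel from the final decreasing phase (`"fit"`, default, falling
  back to the plan's effective rate where the final phase is not decreasing),
  or globally from the plan's effective (`"effective"`) or physical
  (`"physical"`) decay constant.

All three rule choices are recorded in the output manifest. Internally all
times are seconds and all integrals MBq·s; half-lives enter in days and scan
times in hours, converted once at the interface.

## 5. Convolution dosimetry

Absorbed dose is obtained by convolving Ã with a radionuclide-specific
dose-voxel kernel of voxel S-values — the mean absorbed dose to a target
voxel per unit cumulated activity in a source voxel, the voxel-level analogue
of organ S-values. Two engines are provided and tested against each other and
against an explicit source-summation oracle:

* `direct` — shift-and-add over kernel offsets (exact linear convolution with
  zero padding);
* `fft` — zero-padded to full linear-convolution size (n + k − 1 per axis) so
  no circular wrap-around occurs; tiny negative round-off values are clamped
  to zero.

### Kernel values and units

The bundled table (`load_svalue_table()`) stores, for each radionuclide, the
self-dose S-value and the mean first-neighbour S-value at a 4.67 mm isotropic
voxel pitch, in **Gy per MBq·h**. This unit is fixed by physics: for example
the ¹⁷⁷Lu self value of 0.7782 Gy/(MBq·h) at this voxel volume implies a mean
absorbed energy of ≈ 0.13 MeV per decay, matching the ¹⁷⁷Lu mean beta energy,
whereas reading the same number as Gy/(MBq·s) would imply an impossible
≈ 470 MeV per decay. `default_kernels()` converts to the package's canonical
Gy/(MBq·s) by dividing by 3600.

Full 3-D kernels are not published alongside the S-value pairs, so
`default_kernels()` builds synthetic kernels with an isotropic exponential
radial falloff calibrated *exactly* to the published self and first-neighbour
values. Between first neighbours and the kernel edge the falloff is a
modelling choice; since 89–99% of the deposited dose already falls in the
source voxel at this pitch (`neighbour_reduction()`), the tail shape has
little influence on lesion metrics. Measured kernels can be supplied through
the text kernel format (`read_kernel()`/`write_kernel()`) and checked with
`validate_kernel()` and `validate_kernels_report()`.

## 6. Lesion metrics

* **Peak absorbed dose** — the maximum-dose voxel inside the lesion averaged
  with its six face neighbours (in-volume; neighbours outside the lesion
  count, since dose is defined everywhere). This damps single-voxel outliers
  while remaining a maximum-type statistic; a 26-neighbour variant is
  available. The convention used is recorded in the manifest.
* **Cohort profile** — peak doses across lesions are summarised by a
  log-normal maximum-likelihood fit (mean and population standard deviation
  of the logs); the suite cross-checks against `MASS::fitdistr`.
* **cDVH** — voxel doses from all lesions of all patients are pooled with
  their voxel volumes into a cohort cumulative dose-volume histogram: the
  fraction of total disease volume receiving at least each dose.
* **D50** — the largest dose level at which covered volume is still ≥ 50%
  (the upper median of the pooled, volume-weighted voxel doses). With two
  equal-volume lesions at 10 and 20 Gy this convention yields 20 Gy.
* **Treatment comparison** — per-plan median/min/max peak dose, percent
  difference of the median versus the delivered plan, and D50.

## 7. Synthetic cohort generator

`generate_cohort()` produces seeded, fully reproducible patient datasets:

* non-overlapping axis-aligned ellipsoidal lesions (semi-axes 2–4 voxels by
  default) packed with a one-voxel margin; infeasible packings raise an
  explicit error rather than silently overlapping;
* per-lesion uptake amplitudes drawn log-normally; optionally rescaled so the
  whole-volume washout curve extrapolated to t = 0 equals the delivered
  plan's retained activity U·A0;
* voxel TACs rising linearly from zero to the washout curve at 4 h (the
  second scan, so both integration branches are exercised) and decaying at
  the delivered plan's effective rate thereafter;
* a 1/4/24/48/72 h scan schedule on 64³ grids at 4.67 mm, 22 patients with a
  truncated-Poisson mean of 17 lesions each by default;
* optional uniform background and multiplicative Gaussian noise.

The generator emulates the *geometry and kinetics* of quantitative bone-agent
SPECT studies. It deliberately does **not** model SPECT physics — collimator
blur, attenuation, scatter, projection noise or reconstruction artefacts —
nor skeletal anatomy; lesions are ellipsoids on an empty background. Ground
truth (per-lesion amplitudes and rates) is attached to each dataset, and
`ground_truth_dose()` computes the exact closed-form cumulated activity and
the resulting dose analytically, providing an oracle independent of the
scan-sampling and phase-integration code paths.

## 8. Numerical and design choices

* **Canonical units**: seconds and MBq·s internally; days (half-lives) and
  hours (scan times) at the interface. Kernels: Gy/(MBq·s) internally,
  Gy/(MBq·h) in the bundled published-value table (see §5).
* **Open rules made explicit**: head rule, tail rule, minimum-activity
  threshold, peak-dose neighbourhood and the D50 convention are parameters
  with documented defaults, all echoed in the run manifest so any result can
  be traced to the exact rules that produced it.
* **Determinism**: the generator seeds the RNG from its config; identical
  configs give byte-identical pipeline outputs.
* **File formats**: NIfTI (via `RNifti`) for maps and masks, JSON for
  registries and manifests, headered plain text for kernels, CSV for tables.

## 9. Limitations

* The extrapolation assumes target agents share the delivered agent's
  biological clearance; agent-specific plasma kinetics, renal excretion and
  red-marrow self-dose are out of scope.
* Kernels are single-radionuclide, single-pitch, homogeneous-medium (bone
  composition and marrow heterogeneity are not modelled), and their radial
  shape beyond the first neighbour is synthetic (calibrated, but a model).
* Absolute doses from synthetic cohorts depend on generator settings and
  should be read as internally consistent illustrations, not clinical
  predictions.
* Peak dose is sensitive to the neighbourhood convention at lesion
  boundaries; both supported conventions are explicit rather than implicit.
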