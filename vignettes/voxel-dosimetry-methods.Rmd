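---
title: "Voxel-based Y-90 dosimetry: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based Y-90 dosimetry: models, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxdose90)
```

This vignette explains the science the package implements, the assumptions
behind it, and the choices made where the methodology is genuinely open.

## The dosimetry model

### Local deposition

Y-90 is a nearly pure beta emitter with a mean range of a few millimetres
in tissue — short relative to the voxel sizes of clinical emission imaging.
The local deposition method (LDM) therefore assumes each voxel's activity
deposits all of its decay energy in that voxel. Integrated over complete
decay, Y-90 releases 49.67 J per GBq, giving the voxel-wise conversion

$$D\,[\mathrm{Gy}] = \frac{49.67\,[\mathrm{J/GBq}] \times A\,[\mathrm{GBq}]}{m\,[\mathrm{kg}]},
\qquad m = \rho \times V_\mathrm{voxel}.$$

Because the 49.67 J/GBq constant already integrates the full decay, no
half-life or beta spectrum enters the computation; they are deliberately
absent from the package. The LDM ignores cross-voxel energy transport —
dose-kernel and Monte-Carlo dosimetry are out of scope.

`ldm_dose()` implements the conversion. Its `density_g_per_mL` default of
1.03 g/mL is standard soft-tissue/liver density; vendor dosimetry tools do
not all document their assumed density, so it is exposed as a parameter.
`lung_dose()` applies the same single-compartment conversion to the
shunted activity with a default lung mass of 1.0 kg, again configurable
because no consensus mass convention exists.

### Patient-relative calibration

Emission counts have no absolute scale. `calibrate_activity()` rescales
the count volume so the field-of-view total equals the *net* administered
activity — administered minus the residual measured in the vial and
catheter — and zeroes voxels outside the field of view. Conservation
(`total(output) = net activity` to 1e-9 relative) is a tested contract.

### DVH and D-metrics

`dvh()` returns the exact empirical survival curve of the voxel doses in a
compartment on a uniform dose grid (default 1000 levels, an export
resolution only). `d_metric()` never reads the binned curve: with doses
sorted descending, $D_x = d_{(\lceil xn/100\rceil)}$ — the largest dose
received by at least $x\%$ of the volume, so $D_{100}$ is the minimum voxel
dose. The ceiling-index, no-interpolation convention was chosen because it
is exactly checkable against a brute-force counting oracle (and is so
checked, on dozens of random dose maps); published DVH tools differ in
their interpolation and rarely document it.

### T/N and the compartment model

The tumour-to-normal ratio divides the mean tumour dose by the mean
perfused-normal dose. By default the numerator uses the *perfused* tumour
(the treated tumour); a switch selects the whole tumour, since reports of
"tumour dose" in bilobar disease do not always resolve which is meant.
Compartments are binary masks on a shared grid with enforced set
identities (`normal_liver = whole_liver \ tumor`,
`perfused_tumor = perfused ∩ tumor`, …), so a dose report cannot silently
mix inconsistent segmentations.

### Lung shunt fraction

`lung_shunt_fraction()` implements the planar geometric-mean method:
per-organ totals on the anterior and posterior views are combined as
$GM = \sqrt{C_{ant} C_{post}}$ and
$LSF = GM_{lung}/(GM_{lung}+GM_{liver})$. The geometric mean compensates
depth-dependent attenuation when the two views are genuinely opposed
projections.

## Treatment planning

All predicted doses are linear in administered activity, so planning
reduces to scale factors $s_r$ (Gy per GBq per role, from
`dose_per_GBq()`: calibrate to 1 GBq, convert, take compartment means) and

$$A = \min\left(\frac{\mathrm{target}}{s_{tumor}},\;
\frac{\mathrm{limit}}{s_{normal}},\;
\frac{\mathrm{lung\ headroom}}{49.67\,\mathrm{LSF}/m_{lung}}\right).$$

Device-specific defaults: glass targets 250 Gy (HCC) / 200 Gy (metastasis)
with the *whole-liver* normal dose limited to a ceiling inside the
50–90 Gy window; resin targets 100 Gy with *perfused* normal tissue
limited to 40 Gy; lungs 30 Gy per treatment, 50 Gy cumulative. Three open
points resolved here:

* The glass 50–90 Gy window is implemented as a single configurable
  ceiling (default 90 Gy) plus a warning whenever the plan exceeds 50 Gy —
  how the window is adjudicated per patient is a clinical judgement the
  calculator cannot make.
* An unreachable tumour target does not fail the plan: the limiting
  activity is prescribed and `tumor_target_met = FALSE` is flagged (the
  target is pursued "if possible"). Only exhausted cumulative lung
  headroom makes a plan infeasible.
* Shunted activity is *not* subtracted from the hepatic compartments
  before prediction; whether clinical tools do so is undocumented, and the
  effect is second-order at typical shunts (< 10%).

Ties between binding constraints are reported in the fixed priority order
tumour target, normal tissue, lung, for determinism.

## The digital phantoms

`phantom_spec()` / `make_phantom()` build an ellipsoidal liver with
spherical tumours, a perfused lobe split off by a sagittal plane (mirroring
unilobar treatments delineated "with linear lines"), and a lung slab
superior to the liver. Activity is piecewise-uniform: one concentration in
perfused normal tissue, `true_TN` times that in perfused tumour, zero
elsewhere; the hepatic total is `net_activity × (1 − LSF)` exactly, with
the shunted fraction appearing only in the planar simulator's lung slab.

Default anatomy reproduces the typical unilobar cohort: semi-axes
(105, 70, 55) mm give a ~1690 mL liver; one 30 mm tumour gives ~113 mL; the
perfused fraction 0.62 yields a ~1060 mL perfused lobe; default net
activities are 2.35 GBq (glass) and 1.20 GBq (resin); default true T/N
2.32; default LSF 0.05 (clinically typical — shunt fractions themselves
are rarely reported). The truth grid is 2.5 mm isotropic by default: fine
enough to resolve the PSFs being simulated, coarse enough that a phantom
builds in well under a second.

Piecewise-uniform activity is the simplest structure that makes T/N, DVH
and recovery testable, but a uniform tumour cannot exhibit DVH *narrowing*
under blur (its distribution can only widen at the edges). A heterogeneity
knob — log-normal voxel multipliers with unit mean,
`heterogeneity_sdlog` — is therefore provided, off by default, and used
where heterogeneous truth matters (see below).

### Acquisition simulators

`simulate_modality()` resamples the truth activity (count-conserving) onto
the scanner grid, convolves with an isotropic Gaussian PSF whose discrete
kernel is column-normalized (each source voxel redistributes exactly its
own content, so totals are conserved at the field edges), scales to
expected counts, and Poisson-samples on request. Convenience wrappers use
the standard grids — SPECT-like 4.42 × 4.42 × 2.50 mm, PET-like
2.34 × 2.34 × 2.78 mm — with default system resolutions of 12 mm FWHM
(SPECT-like) and 5 mm FWHM (PET-like; the PET value matches the usual
post-reconstruction filter, the SPECT value a typical reconstructed
resolution — neither is a measured system PSF). The count budget
(`counts_per_GBq`, default 1e6) is configurable since clinical count
statistics vary widely.

`simulate_planar()` projects the total-body activity along the
anterior–posterior axis and rebins in-plane with exact area-weighted
redistribution, so organ count fractions are preserved to machine
precision. Attenuation is deliberately not simulated: without it the
posterior projection equals the anterior one, the geometric mean reduces
to the single-view estimate, and the estimator's algebra can be tested
exactly. Consequently the phantoms validate the *estimator*, not the
attenuation compensation it provides on real data.

### What passing tests do and do not show

The phantoms share the real data's structure (compartment geometry,
count statistics, PSF blur, a known shunt) but none of its confounders:
no attenuation or scatter residuals, no respiratory motion, no
registration error, no segmentation variability, no microsphere/MAA
biodistribution mismatch. Recovery within 1e-6 on the clean path shows the
computational chain is exact; the blur experiments show the direction and
rough size of partial-volume effects; neither quantifies accuracy on
patients.

## Geometry and resampling

Grids are axis-aligned with a voxel-centre origin convention in world
millimetres; NIfTI I/O accepts only diagonal, positive sform affines and
rejects shear explicitly. Registration transforms are user-supplied rigid
transforms (Euler angles, degrees, ZYX order) — clinical registration here
is manual, so no automatic registration is provided. Resampling is
tri-linear (nearest-neighbour for masks, which must stay binary), with two
modes: plain interpolation for intensive quantities (dose), and
`conserve_total` for extensive ones (counts, activity), which rescales so
the regridded total matches the input exactly — attempting to "conserve"
dose is an error. Out-of-field voxels sample as zero signal, matching
count images with air background. Tri-linear interpolation is a
documented choice, not a vendor behaviour: the interpolation used by
clinical tools after rigid registration is generally unstated.

Compartment doses are computed on whichever grid the dose map lives on,
with masks resampled to it (the shared-segmentation workflow); dependent
roles are re-derived after mask resampling so the set identities hold
exactly on the new grid.

## The statistics layer

* **Wilcoxon signed-rank** (`wilcoxon_signed_rank()`): zero differences
  dropped (classical convention rather than Pratt's), exact null for up to
  25 untied pairs, otherwise the normal approximation with tie and
  continuity corrections. All-zero differences raise an error.
* **ICC** (`icc_two_way_mixed()`): two-way mixed-effects, single measures,
  from the mean-squares decomposition; both absolute-agreement (default —
  the common SPSS "two-way mixed, absolute agreement" reading) and
  consistency definitions, since reliability reports often omit which was
  used. p-values from the F test of between-subject against residual mean
  squares. Interpretation bands: poor < 0.5 ≤ moderate < 0.75 ≤ good
  < 0.9 ≤ excellent.
* **Bland–Altman** (`bland_altman()`): nonparametric by default — median
  bias with a distribution-free order-statistic CI and empirical
  2.5th/97.5th percentile limits (type-7 quantiles) — because dose-metric
  differences are typically skewed and published asymmetric difference CIs
  indicate percentile-based practice; the classical parametric
  mean ± 1.96 SD limits with t-based CIs are retained.
* **R²** (`ols_r2()`): ordinary least squares of post- on pre-treatment
  values.

`agreement_report()` applies all four per dose metric and device stratum.
No multiplicity correction is applied by default (each p is reported
as-is); Holm adjustment is available behind a flag for reuse.

## Numerical choices and degenerate inputs

* Tolerances: conservation contracts hold to 1e-9 relative; clean-path
  recovery to 1e-6; order-statistic metrics are exact.
* Identity resampling (same grid, identity transform) short-circuits to a
  copy, so no-op pipelines are bit-exact.
* Planar count totals are accumulated in double precision (integer count
  images overflow 32-bit products in the geometric mean).
* Degenerate inputs fail loudly: empty masks, zero count fields,
  zero-variance ICC inputs, constant-x regression, all-zero Wilcoxon
  differences, dose volumes passed to count-conserving resampling.
* In `agreement_report()` a degenerate statistic is flagged in a `note`
  column instead of aborting the whole report.

## Problem sizes

The shipped demonstration configuration uses a 4 mm truth grid (about
48k voxels) and runs the full simulate → LSF → dose → plan chain in
seconds; the default single-phantom grid is 2.5 mm (about 460k voxels) and
runs in a few seconds per modality. Cohort simulation defaults to the
study-scale 27 glass + 20 resin cases on a 3 mm grid. The test suite uses
compact phantoms (4–6 mm grids) throughout so the full suite, including
the brute-force oracle comparisons and the 2000-replicate Wilcoxon
calibration run, completes in about a minute.

## Known limitations

* LDM only; no dose-kernel/Monte-Carlo transport, no BED/EUD.
* No attenuation, scatter or motion in the simulators; planar views are
  unattenuated projections.
* Axis-aligned grids only; no DICOM, no deformable registration.
* Phantom tumours are spheres with at most log-normal texture; no
  realistic anatomy atlases.
* The planner models a single injection; split or segmental
  multi-injection plans are out of scope.
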