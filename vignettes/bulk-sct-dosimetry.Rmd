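---
title: "Evaluating bulk electron-density synthetic CTs for MR-guided adaptive radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating bulk electron-density synthetic CTs for MR-guided adaptive radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

On an MR-Linac, the daily plan adaptation ("adapt to shape") is computed on
the MRI of the day. MRI carries no electron-density information, so a
relative-electron-density (rED) map — a *synthetic CT* (sCT) — must be
attached to it before dose can be calculated. The clinical workflow on the
1.5 T Unity system does this by **bulk assignment**: contours are propagated
from the planning CT to the MRI by rigid registration, and every contoured
region is filled with a single rED value. Three variants of that idea are
compared here, for nasopharyngeal anatomy where air cavities and the cranial
bone make the choice consequential:

* `homogeneity` — the whole body is water (rED 1.0);
* `icru` — air = 0.001 and cranial bone = 1.61 (the ICRU Report 46
  population constants), all remaining regions at the patient-specific mean
  rED from the planning CT;
* `tailor` — *every* region, including bone and air, at its patient-specific
  mean rED.

The evaluation instruments are the ones used clinically: 3D global gamma
analysis (1%/1 mm and 3%/3 mm with a 10% low-dose threshold), the point dose
at the centre of the nasopharyngeal PTV, DVH parameters
(D~mean~, V~100%~, D~98%~, D~2%~, D~max~, D~1cc~), and paired Wilcoxon
signed-rank statistics across the cohort.

Because the underlying patient images are not distributable, the package
ships two complementary data sources:

1. the published per-patient result tables of a 10-patient NPC cohort (as
   plain-text fixtures, `reference_gpr()` and `reference_point_dose()`),
   whose summary rows are always *recomputed*, and
2. a seeded digital head-phantom generator that emulates the anatomy the
   analysis depends on, so the whole pipeline runs end to end with no
   downloads.

## The phantom generator: what it emulates and what it does not

`default_npc_spec(seed)` describes a 128 × 128 × 96 voxel grid at 2 mm
isotropic spacing (the clinical study used 3 mm CT slices and a 2 mm dose
grid; a single 2 mm grid keeps a full cohort run at desk scale while staying
at the clinical dose-grid resolution). The head is an ellipsoid of soft
tissue (~30 HU) wrapped in a cranial bone shell, with a nasopharyngeal air
cavity plus two smaller sinus cavities, four nested/lateral PTVs
(PTV~nx~ ⊂ PTV~1~ ⊂ PTV~2~, plus a nodal PTV~nd~), and a representative OAR
subset (brainstem, spinal cord, both parotids). Gaussian noise (sd 20 HU) is
added inside the body.

Two anatomical features are deliberate, because they drive the physics this
pipeline probes:

* the nasopharyngeal cavity overlaps PTV~nx~ and contains its centroid, so
  the high-dose evaluation point sits at a tissue–air interface, and
* the bone shell fully encloses the head, so every co-planar beam crosses
  bone.

Each seed draws the subject's cavity-air HU from U(−785, −700) and the
cranium HU from U(520, 610). Through the default calibration these bands map
to segmented ROI mean rED of roughly 0.20–0.31 (air) and 1.29–1.35 (bone) —
inside the patient-to-patient ranges reported for NPC cohorts (0.196–0.327
and 1.280–1.362). That is a designed property of the generator, not a
measurement: passing the band check shows the generator is calibrated, not
that real patients are.

The pseudo-MRI is an intensity remap of the tissue classes plus independent
noise, offset from the CT by a known rigid transform (default 3 mm
translation + 2° rotation). No stage uses MR intensities quantitatively —
assignment is contour-driven — so MR realism beyond geometry is not
attempted. There is no dental-artifact simulation, no organ texture, and no
registration *estimation*: the pipeline applies the known transform, so
registration error as a confounder is out of scope by construction.

## HU → rED calibration and segmentation

The default piecewise-linear calibration runs through (−1000, 0.001),
(−300, 0.71), (0, 1.0), (250, 1.12), (1200, 1.72), clamped at both ends. The
true scanner curve of any given clinic differs; it is therefore replaceable
(`read_calibration_curve()`), and every numerical claim in the test-suite is
either curve-independent or stated as a band.

Bone and air are contoured by thresholding (`HU > 250`, `HU < −300`)
restricted to the body, mirroring clinical practice. The manual clean-up a
clinician would apply is replaced by a deterministic morphological closing
(ball radius 1 voxel) and removal of connected components below 0.5 cm³ —
both exposed in `threshold_config()` because the manual step is inherently
irreproducible.

## The bulk maps

`make_assignment_table()` encodes the three strategies;
`build_sct()` lays the values down in precedence order
(body < targets < OARs < bone < air), so that an air cavity keeps its low
density even inside a PTV. The precedence is configurable; the default
reproduces the behaviour that matters at tissue–air interfaces. Synthetic
CTs are built on the MRI grid after contour propagation and resampled back
(trilinearly) to the CT grid for comparison, which also reproduces the
partial-volume-like intermediate rED values at cavity walls that a real
planning CT shows. Under identity registration the tailored map conserves
every non-overlapped ROI's mean rED exactly — a construction invariant the
acceptance suite checks at 1e-12.

## The simplified dose engine

The clinical study used a GPU Monte Carlo engine with full magnetic-field
transport; that is explicitly out of scope. The engine here is the smallest
analytic model that responds to the two mechanisms the comparisons probe:

1. **rED line integrals.** Per beam, the primary dose at a voxel is
   `weight × inverse-square × exp(−μ_eff · d_rad) × penumbra`, where `d_rad`
   is the exact Siddon radiological depth from the source, with a linear
   buildup ramp over the first 1.5 cm of radiological depth. Defaults:
   μ_eff = 0.049 cm⁻¹ (7 MV FFF-like effective attenuation), SAD 1435 mm,
   error-function penumbra with σ = 5 mm at the isocenter plane. Nine
   equidistant co-planar beams, rectangular apertures bounding the projected
   PTV~2~ plus 5 mm, all weights equal.
2. **A magnetic-boundary (electron-return) kernel.** With the field on,
   secondary electrons cannot cross a low-density gap; they are curled back
   into the proximal tissue. The engine models this along each source ray:
   at every sharp rED drop (threshold 0.3), dose is removed on the distal
   side and added on the proximal side with an exponential kernel
   (range 10 mm), scaled by `fraction × (1 − ρ_distal/ρ_proximal)`. The
   relative-drop factor is the package's own choice: a near-void cavity
   (rED 0.001) blocks the electron current almost completely, while a
   partial-density cavity (rED ≈ 0.2) transmits most of it. This is what
   makes the ICRU-constant map underdose the interface point in the same
   direction as the published cohort, where the effect was attributed to the
   electron return effect at the PTV~nx~ centre.

The exported 1D operator `ere_perturbation()` is exactly dose-conserving per
ray (the acceptance suite checks conservation at 1e-9). Inside the 3D engine
the same kernel is applied per-voxel along each voxel's own source ray,
which conserves dose only approximately across rays; the approximation is
acceptable because no comparison integrates dose along single rays.

Plans are normalized once, on the reference (CT-derived) rED map, so that
the PTV~nx~ reference point receives its prescription (70 Gy); the factor is
then frozen and reused unchanged for every synthetic-CT recalculation —
"recalculation only, no re-optimization".

What the engine does *not* model: scatter (μ_eff is effective), MLC
segments and MU optimization, couch and immobilization, charged-particle
transport. Consequently the absolute gamma pass rates and point-dose
magnitudes of the synthetic cohort are milder than the published clinical
values; only directional and ordering statements are claimed, and only those
are asserted by the acceptance suite.

## Gamma, DVH, and point-dose semantics

* **Gamma.** Global normalization to the reference-dose maximum (a
  prescription-normalized mode exists), 10% low-dose threshold, search on an
  interpolated sub-voxel lattice with step Δd/10 inside a ball of radius
  3Δd. Pure voxel-centre gamma overestimates γ on 2 mm grids, hence the
  interpolation; the implementation is exact (branch-and-bound over grid
  cells, with the trilinear range of each cell bounded by its corner
  values), and the test-suite pins it against an exhaustive brute-force
  search on small grids at 1e-9.
* **Point dose.** "Centre of PTV~nx~" is the mask centroid snapped to the
  nearest in-mask voxel (the centroid of a non-convex ROI can fall outside
  it). Differences are percentages of the reference point dose.
* **DVH.** D~x%~ interpolates linearly between the sorted order statistics
  (the type-7 quantile convention); D~1cc~ is the level exceeded by exactly
  1 cm³ of the ROI (125 voxels at 2 mm), reported as D~max~ with a flag for
  ROIs under 1 cm³. ΔDVH follows the sCT − CT sign convention.

## Paired statistics

`summarize_values()` returns the mean and the *sample* (n−1) SD.
`wilcoxon_signed_rank()` implements the asymptotic test the way SPSS-style
software does — zero differences dropped, ties mid-ranked, tie-corrected
variance, no continuity correction — because that is the convention under
which the published p = 0.005 for the tailored-vs-ICRU gamma contrast
reproduces (the exact enumeration gives 0.002 for ten uniformly signed
pairs). The exact method (sign-flip convolution, n ≤ 20) is available and
cross-checked against `stats::wilcox.test`. One reproduction caveat found
while verifying the fixtures: the published point-dose table's summary row
uses the population (n) SD denominator, unlike the gamma table's sample SD;
the fixture tests reproduce each table under its own convention.

## Numerical and design choices

* Fixed LPS frame, 0-based indices, voxel centres as world positions;
  axis-aligned grids, with rigid transforms living in world space.
* Fill values outside a resampled volume's support are unit-specific
  (−1000 HU / 0.001 rED / 0 Gy), so out-of-body space behaves as air; the
  sCT background is 0.001 rather than 0 to avoid degenerate path integrals.
* Mask propagation is nearest-neighbour, intensity propagation trilinear.
* The comparison grid is the planning-CT grid, fixed for all stages.
* Bone wins where morphological closing makes the bone and air contours
  touch (the raw thresholds cannot overlap).
* Cohort default: 10 seeds, echoing the 10-patient clinical cohort. A full
  10-seed study (3 sCTs, 4 dose calculations and 6 gamma analyses per
  subject) runs in a few minutes on one CPU.

## Worked example

```{r example}
library(sctdosim)

ph <- build_phantom(default_npc_spec(1))
red <- hu_to_red(ph$ct)
seg <- segment_bone_air(ph$ct, roi_mask(ph$structures, "body"))
rois <- ph$structures$rois
rois$bone <- list(role = "bone", mask = seg$bone)
rois$air <- list(role = "air", mask = seg$air)
structures <- structure_set(ph$structures$geometry, rois)
summary <- summarize_roi_red(red, structures, hu = ph$ct)

plan <- resolve_plan(plan_spec(), structures)
ref <- compute_dose(red, plan, beam_model(), structures)

doses <- lapply(c(tailor = "tailor", icru = "icru"), function(st) {
  sct <- build_sct(structures, make_assignment_table(st, summary))
  compute_dose(sct$red_map, plan, beam_model(), structures,
               norm_factor = ref$norm_factor)
})
compare_strategies(ref, doses, structures)
```

Or the whole cohort in one call:

```{r study}
report <- run_study(study_config(seeds = 1:10))
print(report)
```

## Known limitations

* The engine is analytic; absolute agreement levels are not comparable with
  Monte Carlo results and are never asserted.
* The ERE kernel's enhancement fraction (0.15) is an assumption recorded in
  the model provenance; no acceptance property depends on its value, only on
  the relative-drop scaling's sign.
* The phantom is topologically, not anatomically, faithful: density
  *topology* (cavities inside targets, bone around everything) is right,
  organ shapes are primitives. Results transfer to real data only insofar as
  the mechanism — bulk density error integrated along beam paths and
  amplified at interfaces — is the dominant one.
* Only rigid, *known* transforms; registration estimation error, neck
  flexion, and inter-scan anatomy change are out of scope.
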