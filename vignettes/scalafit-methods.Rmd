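---
title: "Scalar localization of cochlear-implant electrodes with membrane templates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scalar localization of cochlear-implant electrodes with membrane templates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalafit)
```

## The method

An electrode array inserted into the cochlea should remain in the scala
tympani; crossing the middle plane of the cochlear duct (the "basilar
membrane" plane, osseous spiral lamina included) into the scala vestibuli is
a traumatic event that this package is designed to detect from routine
post-implantation imaging. Because the membrane itself is invisible next to
the metal artifact of the contacts, the method substitutes a *template* of
the membrane mid-surface, chosen to match the patient's cochlear
proportions, and reads each contact's position off the registered template.

The pipeline runs in five steps:

1. measure distances *A* (round-window center to lateral wall at 180°) and
   *B* (lateral wall at 90° to 270°) from four landmarks, take the height
   *H*³⁶⁰, and form the selection index (*A*/*B*)×*H*³⁶⁰;
2. select, from a bank of five membrane templates per side, the one whose
   index is nearest the case's;
3. register the template to the case by the four corresponding landmarks
   with a closed-form least-squares similarity transform;
4. compute each contact's signed distance to the registered surface and the
   spherical-cap fraction of the contact volume lying under it;
5. call each contact ST (fraction ≥ 0.50), intermediate (0.10–0.50) or SV
   (< 0.10), the boundary inclusions being part of the definition.

Agreement statistics (Fleiss' kappa, per-category kappas, bootstrap
confidence intervals, chi-squared proportion comparisons) evaluate rater
tables of such calls.

## The synthetic cochlea

No patient or cadaver images ship with the package; a parametric simulator
serves as data source and ground-truth oracle.

**Geometry.** The duct mid-surface is a ribbon swept along a logarithmic
planar spiral r(θ) = a·e^(−bθ) in a right-handed frame: modiolar axis = +z,
base plane z = 0, θ = 0 at the round-window center, a right cochlea winding
counterclockwise seen from the apex, the left side its exact mirror through
the xz-plane. The height profile is piecewise linear and monotone, pinned so
the rise over the first full turn equals *H*³⁶⁰ (total apical height
defaults to 1.35·*H*³⁶⁰ — a plausible apical rise for human cochleae; only
the relative geometry below ~540° matters to the method). The spiral form
itself is a modeling choice: only landmark-relative geometry enters the
pipeline, and a log-spiral is the standard first-order description of
cochlear coiling.

Given target dimensions the spiral is solved in closed form: the landmark
construction makes B_planar/A_planar = e^(−bπ/2) exactly, so *a* and *b*
follow from *A*, *B*, *H*³⁶⁰ and the ribbon width. A template built from
`spiral_params_from_dims(9.1, 6.8, 2.8)` therefore *measures back* exactly
A = 9.1, B = 6.8:

```{r dims}
tpl <- make_membrane_surface(spiral_params_from_dims(9.1, 6.8, 2.8, turns = 2.75))
unlist(measure_dimensions(tpl$landmarks, 2.8))
```

The nominal duct width (1.0 mm) tapers apically, capped at 1.5× the local
mid-line radius, so the ribbon never reaches the modiolar axis; the taper
only affects the region beyond the 90–540° validation window. Faces are
wound so every normal leans toward +z — the scala-vestibuli side — giving
signed distances a global convention.

**Population.** Cohort dimensions are drawn independently from normal
distributions calibrated to a published pre-implantation population
(A = 9.1 ± 0.30 mm, B = 6.8 ± 0.32 mm, H³⁶⁰ = 2.8 ± 0.21 mm); candidate
template collections use the slightly larger micro-CT-like values
(9.2 ± 0.33, 7.0 ± 0.31, 2.9 ± 0.19). Turn counts are uniform on
[2.5, 3.0], the reported population range. Landmark "click error" is
isotropic Gaussian, default σ = 0.1 mm (sub-voxel for CBCT), configurable.

**Arrays and translocation patterns.** Two array families are built in: a
perimodiolar-style 16-contact array spanning ~420° and a lateral-wall-style
20-contact array spanning ~450°, contacts uniform in arc length, one
0.5 mm contact diameter per model (exact manufacturer pitches are not
modeled; per-electrode calls are indexed by insertion angle, which is what
the classifier consumes). A correctly placed contact sits 0.5 mm below the
membrane mid-line on the scala-tympani side — the membrane-to-center
clearance is an assumption of the simulator, chosen so that a correct
contact (radius 0.25 mm) is fully under the membrane with a 0.25 mm margin.
Two translocation scenarios reproduce the reported failure modes:

* **proximal crossing** — the array crosses the middle plane at an onset
  near 180° (cohort onsets drawn U(165°, 195°), representing "around 180°")
  and stays in the scala vestibuli: the offset switches from −0.5 mm to
  +0.5 mm at the onset, an idealization of a rapid crossing;
* **distal bending** — beyond an onset above 300° (cohort onsets
  U(310°, 380°)) the array rises against the membrane over a 25° ramp and
  holds at +0.26× the contact radius, the signed offset whose cap fraction
  sits mid-way through the intermediate band. Only the lateral-wall-style
  array receives this pattern, matching the reported behavior of the two
  families.

Contact centers get 0.02 mm isotropic jitter (seeded); ground-truth
categories are computed from the *realized* analytic offsets pushed through
the same closed-form cap fraction and thresholds, never through the
mesh-based classifier under test, so jitter cannot invalidate the truth.

**What the simulator does not emulate.** Real segmentations carry
correlated, structured error (partial-volume effects, metal artifact,
inter-rater tracing differences), cochleae deviate from any analytic spiral
(hook region, non-planar basal turn), and arrays bend smoothly rather than
switching offsets. Passing tests therefore demonstrate the *method's*
internal correctness and its robustness to landmark noise and template
mismatch under idealized geometry — not clinical accuracy, which in the
original study design required histology as ground truth.

## Numerical choices

* **Registration** is the closed-form similarity fit (SVD of the 3×3
  landmark covariance); det(R) = +1 is enforced, so a reflection is never
  fitted. A wrong-sided correspondence instead surfaces as a large residual
  plus a chirality warning (emitted when the rejected improper fit would be
  10× better); side-matched mirrored templates are the intended remedy.
  Uniform scaling is on by default — absorbing cochlear size differences is
  the point of the method — and the classifier converts template-frame
  distances back to case millimeters through the fitted scale, making the
  inverse-transform route identical to transforming the template forward.
* **Mesh distance** is an exact closest-point query (interior projection vs
  the three edges, minimized per face, then over faces); the sign comes
  from the nearest face's normal. Queries whose nearest point lies on an
  open boundary edge are flagged `edge` (tangent-plane extrapolation) but
  still answered, so contacts near the basal crop or beyond the apical end
  of a cropped template are classified rather than refused.
* **Spherical-cap fraction** is evaluated in the dimensionless form
  (1−x)²(2+x)/4 with x the signed distance over the radius, which is exact
  in floating point at the anchor values 0, ±r and r/2 (fractions 1/2, 0, 1
  and 5/32). "Percent of the electrode under the membrane" is not given a
  geometric definition in the clinical protocol; the spherical-cap volume
  fraction is this package's operationalization — closed-form, rotation
  invariant and strictly decreasing in the signed distance.
* **Bank construction** fits a normal distribution to the reference index
  values and picks candidates nearest the 10/30/50/70/90th percentile
  targets (equal-mass quintile midpoints — the original selection "according
  to the Gaussian distribution" does not state its quantiles), without
  replacement, ties to the lower index; picks are re-sorted so the bank is
  strictly increasing. Out-of-range case indices clamp to the extreme
  template with a warning: every case gets a template.
* **H³⁶⁰** is supplied per case as a scalar (simulator truth, or a plane
  measurement made by the user); plane-based measurement is viewer work
  outside this package's scope.
* **Kappa intervals** default to a seeded item-bootstrap percentile interval
  (2000 resamples), valid for the per-category collapses where asymptotic
  variances are shaky; the Fleiss–Nee–Landis large-sample variance is
  available as `method = "asymptotic"`. Tables with fewer than 5 items are
  refused an interval. The chi-squared proportion test is Pearson without
  continuity correction by default (a flag restores Yates), with a warning
  attached when an expected cell drops below 1.

## Validation design and problem sizes

The test suite ties the simulator to the classifier (a correctly placed
array must be fully under the membrane), checks every closed-form quantity
against independent oracles (a scalar region-based closest-point algorithm;
the pairwise-agreement formulation of Fleiss' kappa; `vegan`'s Procrustes
rotation for the landmark fit), and exercises the pipeline end to end:
100-case cohorts at σ = 0.1 mm landmark noise for per-electrode accuracy
and translocation detection, and a 22-candidate bank serving a 100-case
cohort for the cropped 90–540° membrane-to-membrane fit distance. Templates
are meshed at 5° with 7 radial samples (~1400 vertices), which keeps a full
cohort run under a minute on one core while mesh discretization error
(≈ 5 µm sagitta at the basal turn) stays orders of magnitude below every
decision threshold. `scripts/acceptance.R` re-runs these computations from
scratch under a caller-supplied seed.

## Known limitations

* The analytic spiral has no hook region; the 0°–90° segment is geometric
  extrapolation, which is why the validation window starts at 90°.
* Classification quality for intermediate contacts is the tightest margin
  in the system: the INT band spans only ±0.15 mm of signed distance for a
  0.5 mm contact, so sub-0.1 mm registration accuracy is required — visible
  in cohort runs as occasional INT/ST flips under landmark noise.
* Fleiss' kappa assumes a fixed rater count per item; tables with missing
  ratings are rejected rather than reweighted.
* The simulator prescribes translocation geometrically; it does not model
  insertion mechanics, so it cannot generate unanticipated failure modes.
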