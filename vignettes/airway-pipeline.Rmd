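---
title: "Plane-delimited airway volumetrics and mandibular kinematics: methods"
author: "airwaymorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plane-delimited airway volumetrics and mandibular kinematics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwaymorph)
```

## The measurement problem

Mandibular advancement — whether by a removable oral appliance (MAD) or by
two-jaw orthognathic surgery (MMA) — changes the shape of the pharyngeal air
column. Quantifying that change from cone-beam CT (CBCT) requires a chain of
geometric steps, each of which can silently bias the result: both timepoints
must be expressed in one anatomical frame, the oropharynx must be delimited
reproducibly, and "volume" and "surface area" must have a single, testable
definition. `airwaymorph` implements that chain as composable functions with
a synthetic-phantom layer that supplies analytic ground truth, so every
geometric operation is validated end-to-end rather than by visual inspection.

All geometry lives in RAS millimetres (+X right, +Y anterior, +Z superior);
every reader converts on load (NIfTI headers via their sform, Slicer
fiducials via the declared RAS/LPS dialect). One unambiguous frame removes a
whole class of sign errors from downstream rules.

## Head orientation and registration

The oriented head frame is built from four landmarks: the transporionic axis
(PoR–PoL) fixes the lateral direction, the Frankfurt horizontal is the plane
through the two porions and the mean of the orbitale landmarks (averaging
left/right orbitale reduces the classical four-point Frankfurt fit to a
deterministic three-point plane), and the origin is the mid-transporionic
point. In the oriented frame the Frankfurt plane is perpendicular to +Z and
the midsagittal plane is {X = 0}. The frame is idempotent: applied to
already-oriented landmarks it returns the identity to numerical precision.

Two registration paths map the follow-up scan into the baseline frame:

* **Landmark least squares** (default): the closed-form SVD (Kabsch) rigid
  fit over named cranial-base fiducials. No scaling; a configuration whose
  best linear fit is a reflection is rejected rather than silently flipped.
  This path is exactly reproducible and is what the pipeline uses unless
  told otherwise.
* **Voxel-based**: both binary volumes are Gaussian-smoothed (default
  bandwidth 2 voxels), and a 6-DOF Nelder–Mead search (multi-resolution,
  coarse-to-fine, fixed iteration budget, deterministic) maximises the
  normalized cross-correlation of the smoothed fields, optionally restricted
  to a cranial-base region mask. On phantoms with curved surfaces this
  recovers programmed motions to roughly a tenth of a degree and a few
  hundredths of a millimetre at 0.8 mm voxels.

Masks are carried between frames in two deliberately different ways.
`apply_transform()` resamples by nearest neighbour onto the original grid —
binarity-preserving, but lossy (round-trip Jaccard ≥ 0.98 on smooth shapes)
and only valid while the object stays inside the field of view.
`transform_grid()` instead composes the rigid transform into the
voxel-to-world affine: exact, lossless, valid for arbitrarily large motions,
at the price of grid axes that are no longer world-aligned. All measurement
code accepts general affines, so the pipeline uses the exact path
internally.

## Delimiting the oropharynx

Three parallel planes delimit the regions: the base plane contains basion
(Ba) and the posterior nasal spine (PNS), the other two pass through the
C2I and C4S landmarks with the same normal. Two points do not determine a
plane, so the base plane is made unique by requiring perpendicularity to the
midsagittal plane — its normal is the in-sagittal perpendicular of the
Ba→PNS direction, oriented superiorly. Plane offsets must be ordered
base > C2I > C4S or the landmark set is rejected.

**Volume** is voxel-centre counting in half-open slabs `[lower, upper)`
along the common normal, times the voxel volume. No partial-volume
weighting: the half-open convention makes the superior and inferior
oropharynx an exact partition of the total region (the invariant
`superior + inferior == total` holds identically, not within a tolerance),
and accuracy is governed by the acquisition's 0.4 mm voxels.

**Surface area** is measured on a triangulated iso-surface (level 0.5) of
the mask, extracted by marching tetrahedra over a Gaussian-smoothed copy of
the binary grid (default 1 voxel bandwidth — smoothing restores sub-voxel
surface placement that a binary grid cannot carry; meshing the raw binary
field is available by setting the bandwidth to zero). Each triangle is
assigned to a region by its centroid's slab, so region areas also partition
the total exactly. The artificial planar caps created by the delimitation
are **not** added: caps are artefacts of where the planes were drawn, not
anatomy. On a cylinder the measured lateral area is within ~0.7% of
2·pi·r·h at 0.4 mm voxels, comfortably inside the 3% validation band; if a
different tool includes cut caps its areas will differ by exactly the cap
areas.

## Mandibular kinematics

Displacement is read directly off the B point: `delta_ap = Y(T1) − Y(T0)`
(positive anterior) and `delta_si = Z(T1) − Z(T0)` (positive superior).

"Pitch" is rotation about the left–right axis. Each directed line (condylion
→ gonion for the ramus, condylion → B for the anterior body, each side
separately) is projected onto the midsagittal YZ plane and its orientation
angle taken as `atan2(dz, dy)`; the reported rotation is the wrapped angle
difference T1 − T0 in (−180, 180]. The projection gives the angle a sign —
positive is counterclockwise seen from the patient's right (anterior
landmark rotating superiorly), so an appliance-style opening rotation is
negative and a surgical counterclockwise rotation positive, matching the
clinical convention. A true 3D angle between lines would lose exactly this
sign. For any pure pitch motion the measured angle equals the programmed
angle to 1e-6 degrees on all four lines; pure translations measure zero.
Note one genuine approximation: a common yaw of both timepoints perturbs
the projected angle at second order (about 0.001 degrees for a 1 degree
yaw), so pitch is frame-stable, not frame-invariant, under out-of-plane
rotations. Left and right sides are reported separately *and* averaged;
pooling is justified in the statistics layer by the left-vs-right paired
test.

## Reliability statistics

Intra-rater repeatability over two landmarking sessions uses:

* **Dahlberg's casual error** `d = sqrt(sum (m1 − m2)^2 / 2n)`, in the
  measurement's units; under i.i.d. Gaussian session noise it estimates the
  session SD.
* **Relative random error** `100 · d / grand mean` — the grand mean of both
  sessions is used as the denominator because it is the only symmetric
  choice.
* **ICC**, single-measurement form from the two-way ANOVA decomposition.
  The default is ICC(3,1) (two-way mixed, consistency): one fixed examiner
  re-measuring the same subjects is exactly the two-way mixed design, and
  consistency is the standard intra-rater choice. ICC(2,1) (absolute
  agreement) is available where a session mean-shift should count against
  reliability.

## Cohort statistics

The statistical layer mirrors a paired two-group treatment study:

* **Student's t** between groups is the pooled-variance form (that is what
  the name means); Welch is a flag, not the default. Summary triples
  `(n, mean, sd)` are accepted so printed tables can be tested directly.
* **Paired t** within groups, on T1 − T0 differences.
* **Normality** by Kolmogorov–Smirnov with estimated mean and SD. Estimated
  parameters make the textbook KS p-value anticonservative, so the default
  p comes from a seeded Lilliefors Monte-Carlo simulation of the null
  (10^4 replicates by default, cached per sample size); the uncorrected KS
  p is available behind a flag.
* **Age adjustment**: the two-group comparison adjusted for age is a linear
  model `y ~ group + age` with Type II F tests, reported as the age-factor
  and group-factor p-values. Type II is the appropriate decomposition for
  two non-nested main effects without interaction.
* **Pearson correlation** with the exact t transform; **chi-square** for
  the 2×2 sex table *without* continuity correction — the uncorrected
  statistic is what reproduces the study-scale worked example (9/8 vs 7/10
  gives p = 0.492).
* **Sample size** for the paired design from the noncentral t distribution:
  the smallest n whose two-sided paired-t power reaches the target, no
  normal approximation. With the published effect (1261.6 ± 1476.2 mm³,
  alpha 0.05, power 0.90) the exact answer is 17 pairs (power at 16 is
  0.891).
* **Treatment success** for the appliance group: post-treatment AHI < 10
  events/hour or a ≥ 50% reduction from baseline.
* **No multiplicity adjustment** is applied anywhere — deliberately
  mirroring the study design — but every report records the number of tests
  run so a reader can apply their own.

## The phantom layer: what it emulates and what it proves

`make_airway_phantom()` voxelizes a vertical tube (constant or
piecewise-constant radius, optionally tilted delimiting planes, optional
spherical markers) and places all landmarks so that every region measurement
has a closed-form answer; `make_mandible_case()` applies a programmed rigid
motion to a realistic landmark template; `jitter_landmarks()` draws seeded
Gaussian repeat landmarkings; `simulate_cohort()` draws two-group cohorts
whose baseline levels, change effects and change-score correlations default
to the published study scale (n = 17 per group, airway volumes near
13 000 mm³, appliance-group pitch near −4 degrees, and so on). Because the
airway change-score SDs are not published, they are derived from the
printed baseline/follow-up SDs under a within-subject T0–T1 correlation of
0.8, a typical longitudinal value chosen once. The published correlation
matrix is sparse; unpublished entries default to values chosen once to keep
each group's target matrix positive definite (the simulator refuses
non-positive-definite targets rather than silently repairing them). AHI is
simulated for the appliance group only — in the emulated design the
surgical group has no sleep-study data.

Numerical design choices worth knowing about:

* **Grid alignment.** The tube axis sits at a quarter-voxel offset from the
  voxel-centre lattice. Centring the axis exactly on a voxel centre is a
  degenerate alignment — for r/spacing = 25 about twenty voxel centres lie
  exactly on the rim of the cross-section circle and are all counted,
  biasing the digitized area by +0.6% — while a generic offset keeps the
  in-plane digitization error near 0.1%.
* **Slab-height quantisation.** A 25 mm region at 0.4 mm spacing spans 62.5
  voxel layers, so half-open counting must measure 24.8 or 25.2 mm — a
  ±0.8% height error no algorithm choice can remove at fixed spacing. The
  two sub-regions receive opposite signs, so the total is nearly exact and
  each sub-region lands within 1%.
* **Convergence.** For one fixed grid alignment the error versus voxel size
  oscillates (the height quantisation and the lattice-count fluctuations of
  the disc do not shrink monotonically through a particular alignment), so
  the convergence property is asserted on the *mean absolute error over
  seeded random grid placements*, which decreases monotonically over
  spacings 1.0, 0.8, 0.6, 0.4 mm — that is the statement that is actually
  true of the estimator.
* **Registration phantoms.** A plain tube is rotation-symmetric about its
  axis and its flat end caps quantize coherently (they sit in a single
  voxel layer), which makes one rotation unobservable and biases axial
  translation by up to half a voxel. Registration tests therefore use a
  tube with spherical caps plus two off-axis marker spheres: curved
  surfaces everywhere, all six degrees of freedom observable, voxelization
  error decorrelated. Analytic airway ground truth applies to the
  marker-free tube only.
* **Moved "second scans" are re-voxelized analytically** (the indicator
  function is evaluated at inverse-transformed voxel centres) rather than
  resampled from the baseline grid, exactly as a real second acquisition
  samples moved anatomy; resampling would add nearest-neighbour noise that
  is an artefact of the test, not of the method.

What passing phantom tests does *not* show: real airway segmentations have
irregular cross-sections, open nasopharyngeal and laryngeal ends, soft
tissue motion between scans, and segmentation-threshold variability. The
phantoms validate the geometry and statistics of the pipeline, not the
segmentation step (masks are inputs here, as in the emulated workflow).

## Problem sizes and runtime envelope

The shipped tests run the cylinder closure at 0.4 mm (grid ≈ 61×61×151),
voxel registration on 0.8 mm phantoms (≈ 51×51×101, twenty seeded motions),
paired-t calibration over 2000 null draws at n = 17, correlation recovery
over 500 seeded cohorts, and ANCOVA null calibration over 500 fits at
n = 200. These sizes were chosen so the full suite completes in a few
minutes on a single core while leaving each statistical band a comfortable
sampling-error margin.

## Known limitations

* Only rigid geometry: no deformable registration, no soft-tissue model.
* The supplementary landmark definitions of the emulated protocol are not
  public; landmark semantics follow standard cephalometric usage and the
  phantom places landmarks by construction.
* Surface areas exclude delimitation caps by design; numbers from tools
  that include caps differ by exactly the cap areas.
* The voxel-registration similarity (smoothed-mask NCC) targets binary
  segmentations; grayscale CBCT registration would want a histogram-based
  metric.
* Pitch is exactly invariant under in-plane (pitch + translation) frame
  changes but only first-order stable under large common yaw/roll.
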