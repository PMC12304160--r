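---
title: "Measuring the infant nasolabial region on 3D surface meshes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the infant nasolabial region on 3D surface meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(naso3d)
```

## The measurement problem

Cleft lip surgery needs a quantitative description of the *normal* infant
nose and upper lip at the age when primary repair happens (3 to 9 months),
so that a patient's morphology can be compared against an expected value
for their age and sex. `naso3d` implements the measurement side of that
programme as an open engine: given a triangle mesh of the nasolabial
region (in millimetres) and a set of named anatomical landmarks placed on
it, the package computes a battery of 84 parameters:

* **32 distances** (D1--D32): direct lengths between landmark pairs, plus
  four *perpendicular lengths* -- the distance from a point to the
  infinite line through two other landmarks. These encode effective nasal
  length (pronasale to the nasion--subnasale line), dimple depth, and the
  right/left vermillion convexities.
* **32 surface curves** (S1--S32): lengths of curves constrained to the
  mesh surface, which capture the convexity information a straight chord
  ignores (volumetric nasal height, nostril circumferences, volumetric
  vermillion lengths, ...).
* **2 angles**: the columellar angle (a two-directional angle between the
  cM--sn axis and the commissure line, folded into [0°, 90°]) and the
  vermillion angle (the three-point angle chR--ls--chL).
* **18 indices**: dimensionless ratios -- curve over chord (all ≥ 1 by the
  triangle inequality), right over left (symmetry indices), and their
  averages.

The 33 landmarks are the standard nasolabial set (nasion `n`, subnasale
`sn`, pronasale `prn`, alar curvature bases `acbR/acbL`, alare `alR/alL`,
columella high points `cR/cL/cM`, inner/outer alare, subalare, medial alar
base `mab`, columella base `cb`, cheilion `ch`, crista philtri `cph`,
labrale superius `ls`, stomion `sto`, vermillion--mucosal junctions `vmj`,
prolabiale `prl`, superior labial sulcus `sls`, lateral vermillion `lv`).
Landmark placement itself is a human task guided by light reflections in
an inspection tool; the engine consumes placed landmarks, and additionally
offers geometric derivations for the five landmarks that have constructive
definitions (`prn`, `sls`, `lvR`, `lvL`, `cM`), reporting the discrepancy
to the user's placement for quality control.

## Surface curves as geodesics

The source methodology draws its surface curves in interactive inspection
software, which does not specify an algorithm. The only operator-free,
reproducible reading of "a curve positioned directly on the mesh between
two landmarks" is the *shortest* such curve -- a geodesic. `naso3d`
computes piecewise geodesics through the registry's waypoint sequences
(closed for the nostril circumferences S6/S7), so composite curves are
exactly additive (S3 = S1 + S2, S12 = S10 + S11).

The geodesic engine has three stages:

1. **Dijkstra on a Steiner graph.** Graph nodes are the mesh vertices plus
   3 evenly spaced extra points per edge; all node pairs on a common face
   are connected with straight-line weights. The shortest graph path gives
   a corridor and an upper bound within a fraction of a percent.
2. **Closed-form straightening.** Each interior path point constrained to
   a mesh edge is moved to the optimum obtained by unfolding its two
   neighbours about that edge (classical string pulling), with
   over-relaxed red--black sweeps.
3. **Geodesic-shortening flow (C++).** The path is resampled to a fixed
   count of 64 points per segment and evolved by midpoint over-relaxation
   with local re-projection onto the mesh, until its length is stationary.
   The fixed point is a discrete geodesic *independent of the corridor*
   Dijkstra happened to return.

Two further safeguards matter in practice. First, near-equal alternative
routes make the Dijkstra corridor depend on the search direction, so every
segment is solved from both endpoints and the shorter refined result kept;
this also makes mirror-image inputs give exactly mirrored curves. Second,
a path running along a ridge line (for example the mid-nasal curves of a
perfectly symmetric face) is a *saddle* of the length functional: the flow
will happily converge to it, yet slightly shorter stable geodesics run
beside the ridge. Each refined segment is therefore probed with a sideways
kick (along tangent × surface normal, in both directions) and the
shortest stable result kept. The probe frame is built from the geometry,
so the whole pipeline is equivariant under rigid motion, mirroring and
scaling; in tests the full 84-parameter battery is reproducible under
random rotations to ~1e-9 mm, far inside the 1e-4 mm claim, and exactly
mirror-consistent. `probe_saddles = FALSE` disables the probe when speed
matters more than the last ~0.01 mm of tightness.

Accuracy was validated against closed forms: on planar grids the engine
reproduces chords to ~1e-12 mm; on spheres, cylinders and a hemispherical
"nose" at the default refinement the worst error is about 0.25% (mostly
the irreducible faceting error of the mesh itself), decreasing
monotonically with refinement. An independent edge-graph Dijkstra (no
Steiner points, no refinement) upper-bounds every result in the test
suite.

Fixed numerical choices: 3 Steiner points per edge; 64 resampled points
per segment; flow over-relaxation 1.7 with a 50,000-sweep cap, stopping
when the largest point move falls below 1e-9 of the segment length or the
length is stationary to 1e-11; kick amplitude min(8% of segment length,
1.5 mean edge lengths); projection tolerance for "on surface" 0.5 mm (the
scanner-noise scale), configurable.

## Reading the parameter table

Where the printed definitions are ambiguous the registry fixes one
reading, recorded here:

* Perpendicular lengths use the *infinite line*, not the segment: on
  infant anatomy the foot point of D4/D16/D27/D28 can fall slightly
  outside the chord.
* The dimple-depth anchor "acp" is read as prolabiale (`prl`), consistent
  with the `sls` definition ("furthest from a direct line connecting sn
  and prl").
* D27/D28 use the ch--cph line of their own definition even though the
  `lv` landmark definition references the ch--ls line; the `lv` derivation
  helper uses ch--ls as printed there, and the QC report surfaces the
  discrepancy.
* "stos" in the vermillion-height curves is read as `sto`; no separate
  landmark of that name exists.
* The battery has 32 surface curves (one summary sentence says 33; the
  table and the stated total of 84 parameters say 32).
* The alar convexity index follows the verbal definition,
  (S4 + S5)/(D5 + D6); the symbolic one-liner printed beside it divides
  by a curve and is treated as a typographical slip.
* The soft-tissue mouth-to-nose index divides mouth width by the *wider*
  of nasal base width (D2) and alar width (D3).
* S25/S26 ("chR--ls ... touching cphR") run through cph as an interior
  waypoint; S6/S7 are closed loops through (cb, mab, ali) in that cyclic
  order.

Indices are only reported when all of their inputs were computed; a zero
denominator yields an explicit `undefined-index` status. Missing landmarks
make the affected parameters `skipped-missing-input` with the missing ids
named -- partial landmark sets are a supported workflow, never an error.

## Alar base typing

The three alar-base configurations are classified per side from the
spatial relationship of the medial alar base (mab), the columella high
point (c) and the columella base (cb). "More lateral/medial" is
formalized as the unsigned offset from the morphological midsagittal
plane -- the plane through n, sn and prn, oriented so the right cheilion
has positive offset. Type III ("direct transition", mab identical to cb)
is detected first, as coincidence within 0.5 mm; otherwise mab more
lateral than c by over 0.1 mm is Type I, more medial Type II, and offsets
inside that dead-zone are reported `indeterminate` rather than forced --
reproducibility beats forced classification. Sides are classified
independently; a whole-nose type is reported only when they agree
(`discordant` otherwise), since no discordance rule is published. Both
tolerances are arguments.

## The reference-statistics layer

* **Growth models.** Per parameter and per sex, a least-squares polynomial
  regression of value on age in months (ages use the 30-day-month
  convention, `age_months(m, d) = m + d/30`). The default degree is 1: the
  published cohort spans only six months, and its descriptive statistics
  are consistent with locally linear growth; the degree is an argument
  where curvature is wanted. The residual SD feeds z-scores,
  `(observed - predicted)/SD`; predictions outside the fitted 3--9 month
  range carry an explicit extrapolation flag. An exact fit (residuals at
  float noise) reports a true zero residual SD.
* **Reliability.** Two-way intraclass correlations from the mean-square
  decomposition: ICC(C,1), consistency, for intra-rater comparisons
  across occasions, and ICC(A,1), absolute agreement, for inter-rater
  comparisons -- single-measure forms, because individual landmarkings are
  compared. Interpretation bands follow the published cut-points: < 0.40
  poor, 0.40--0.75 substantial, > 0.75 excellent (0.75 itself is
  substantial). Percentage agreement at a tolerance (default 1 mm)
  averages over all unordered rater pairs and subjects, as no pairing rule
  for three raters is published. Pearson's r completes the intra-rater
  picture.
* **Imputation.** Chained-equations predictive mean matching, written
  in-package: each incomplete variable is regressed on sex, age, birth
  weight and all other quantitative variables at their current fill-in;
  coefficients are drawn from their Bayesian posterior; each missing cell
  receives the observed value of a donor sampled from the `k = 5` nearest
  predicted means; `maxit = 10` iterations, `m = 5` imputations. PMM never
  fabricates out-of-support values (robust to nonlinearity and outliers),
  observed cells are preserved bit-exactly, and a fixed seed makes the
  output bit-reproducible. Correlated length parameters are visited as one
  block by default; blocks are an argument.

## Synthetic data: what it emulates, and what it does not

No infant scans are distributable, so the package generates every input
its tests need.

* **Analytic fixtures** (plane, sphere, cylinder, hemispherical nose)
  carry closed-form geodesic and chord lengths for every declared point
  pair, at three nested refinement levels.
* **Parametric faces**: a smooth height field (facial dome + superelliptic
  nose bump + alar and columellar ridges + vermillion lip ridge + philtrum
  dimple) sampled on a grid whose lines pass through every landmark, so
  all 33 landmarks are exact on-surface mesh vertices. With
  `asymmetry = 0` mesh and landmarks are exactly mirror-symmetric about
  x = 0, including the triangulation pattern. The alar-type target places
  mab well lateral of c (Type I), medial of it (Type II), or coincident
  with cb (Type III); asymmetry jitter deliberately leaves the lateral
  positions of the typing triplet untouched, so the declared type remains
  a generator invariant. Template dimensions give clinically plausible
  magnitudes (vermillion lengths around 17--19 mm, philtrum around 12 mm,
  columella around 5 mm).
* **Cohorts**: subjects aged 3--9 months, sex ratio 13:25 male, birth
  weight N(3400, 450) g, parameter values
  `intercept + slope·age ± sex_offset + N(0, sd)`. Default growth truths
  are calibrated so the expected value at the cohort mean age of 4.6
  months matches the packaged reference-table means, with slope
  0.3 mm/month, sex offset ±0.15 mm and the published observed SDs --
  calibration is documentation of plausible scale, not a fitted claim.
  Missingness injection is MCAR or MAR-on-age (probability increasing
  with age, emulating age-dependent dropout).

The face generator is stylized, not photorealistic: it has the right
differential-geometric features (ridges, grooves, convexities) at the
right scales, which is what the battery exercises. Passing tests
demonstrate that the *engine* is correct and invariant; they do not
demonstrate landmark placeability on real scans, scanner noise behaviour
beyond the modelled smooth bumps, or clinical validity of the reference
values.

## Problem sizes used by the packaged checks

The test-suite and the acceptance script run the battery on faces with
about 2,000--4,500 triangles, 20 random rigid motions, 100 randomized
faces for the curve-dominance sweep (saddle probing off there -- the
dominance property is refinement-independent), 30 generator-targeted
faces for alar typing, cohorts of 120--300 subjects, and 5-fold
imputation at 20% missingness. These sizes were chosen so each property
is measured well inside its tolerance while a full run stays in the
minutes range.

## Known limitations

* Geodesic accuracy is bounded by mesh faceting; at clinical scan
  resolutions (sub-millimetre edges) that bound is far below scanner
  noise, but very coarse meshes will bias curves short.
* The engine reads surface curves as geodesics. Operator-drawn inspection
  curves may deviate from geodesics where the operator follows a visual
  feature rather than the shortest path; the polyline of every curve is
  returned so such deviations can be audited.
* Growth models are per-sex polynomial least squares -- no mixed effects,
  no longitudinal correlation, matching the cross-sectional design they
  summarize.
* The published clinical reliability values and cohort means derive from
  scans that are not deposited; the packaged reference table reproduces
  the printed summary statistics and the statistics layer reproduces the
  published *methodology*, but re-deriving those clinical numbers is out
  of scope by construction.
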