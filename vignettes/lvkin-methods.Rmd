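---
title: "Boundary prediction and wall kinematics in lvkin: models, phantom, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary prediction and wall kinematics in lvkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: the boundary
parameterization and the three prediction models, the synthetic phantom
that stands in for real 4D ultrasound cohorts, the numerical choices made
where the design was genuinely open, and what the passing test suite does
and does not establish about real data.

## The prediction problem

A 4D cardiac ultrasound recording of a mouse is a stack of short-axis
grayscale images across slices and time. The quantity of clinical
interest is the motion of the left-ventricular wall — the endocardial
(inner) and epicardial (outer) boundaries — over one cardiac cycle.
`lvkin` reduces boundary tracking to a fixed-dimensional regression
problem through a structured parameterization: 48 anchor points, the
cross product of

* six rotations about the long axis, θ ∈ {30, 90, 150, 210, 270, 330}
  degrees counterclockwise from +x (the septal wall lies on −x, the
  standard radiological orientation),
* two boundaries (endo, epi), and
* four short-axis slices at 25, 50, 75 and 100% of the apex-to-base
  distance.

Each anchor's state at cycle phase *t* is its radial distance from the
central z-axis, in mm. Because the apex and base move axially through
the cycle, the four slice planes are re-interpolated per frame from the
per-frame apex/base track (`extract_slices()`), which compensates
through-plane motion. Real recordings must first be rigidly reoriented
into this standard frame; the package takes that transform as user input
(`rigid_transform()`, `apply_rigid_transform()`) since no automatic
reorientation is part of the method. Phantom data are generated
pre-aligned.

## Regressors: image scores and a periodic time basis

**Image block.** Frames are vectorized row-major and compressed by PCA
(`fit_image_basis()`). The components are the leading eigenvectors of the
training covariance; when pixels outnumber samples the decomposition runs
through the n×n Gram matrix, which gives identical leading components at
a fraction of the cost. Intensities are used as-is — no per-image
normalization — because the speckle statistics themselves carry boundary
information and any normalization would be an extra, unforced modeling
decision. The basis (mean and components) is always fit on training
images only and refit inside every cross-validation permutation;
`test-features.R` checks that corrupting held-out images cannot move the
basis.

**Time block.** The "smooth average path" of an anchor across the cycle
is modeled by a cubic B-spline basis over cycle phase with uniform knots,
8 basis functions by default, wrapped periodically so value and first
derivative are continuous across the end-diastole wrap
(`time_basis()`, `evaluate_time_basis()`). Two choices deserve
justification:

* *Periodic, because the cardiac cycle is periodic* — a clamped basis
  would allow a spurious discontinuity between late diastole and the next
  end-diastole.
* *Unpenalized least squares rather than a true smoothing spline* — the
  models are fit by ordinary least squares throughout, so the time basis
  enters as a plain basis expansion; with 8 functions over 16–40 frames
  the basis itself provides the smoothing, and no roughness penalty (or
  its tuning parameter) is introduced.

Because periodic B-splines form a partition of unity (each row of the
evaluated basis sums to 1), the basis spans constants and **no intercept
column is added** to any design matrix: an intercept would be exactly
collinear.

## The three model variants

All variants fit, independently for each of the 48 anchors, a linear
model of the anchor radius by least squares (`fit_boundary_model()`):

1. **Per-slice** (variant 1): the image block holds the *k* PCA scores of
   the anchor's own slice; four separate per-slice PCA bases are fit.
2. **Combined** (variant 2): one PCA of the four slices of a frame
   concatenated into a single vector. This is a joint decomposition of
   the concatenated pixels, not a concatenation of per-slice scores — the
   combined representation should be free to spend its components on
   whole-heart modes (overall size, global contraction phase) rather
   than four copies of slice-local modes.
3. **Assisted** (variant 3): variant 2 plus one scalar coefficient on an
   annotation column that repeats, for every row of an animal, that
   animal's true radius of a single *assist anchor* at its first frame
   (end-diastole). The default assist anchor is the endocardial anterior
   mid-ventricle point (θ = 90°, z = 0.5), configurable.

Least squares is solved by SVD with a minimum-norm fallback
(`.lstsq()`): in small cross-validation permutations the candidate
component count can approach the row count, and a pseudoinverse fit
degrades gracefully (with a warning) instead of failing. One *k* is
shared by all 48 anchors of a fitted model; the cross-validation harness
selects it per permutation on the validation split, which matches the
granularity at which the model is actually deployed.

The rationale for variant 3 is identifiability, not capacity: with
between-animal heart-size variation, image scores of an unseen animal
often determine the *shape* of the radius curve better than its *level*.
A single end-diastolic annotation pins the level. The package's
`generate_linear_cohort(image_signal = "noise", size_sd = 0.3)` isolates
exactly this situation — images carrying no size information — and
variant 3 beats variant 2 on held-out animals there (`test-models.R`).

## The 4D mesh

`build_lv_mesh()` interpolates 48 anchor radii per frame into two closed
surfaces sampled 60 × 60 × 60 (angle × apex-to-base × cycle time),
interpolating in a fixed axis order:

1. **Angle**: a closed periodic cubic spline through the six control
   radii (C² across the 360°→0° wrap). A Hobby-style tension-based
   closed Bézier curve is available behind the same interface
   (`engine = "hobby"`); both engines interpolate the control points, but
   only the periodic polar spline reproduces a circle exactly, so it is
   the default.
2. **Apex-to-base**: a natural cubic spline through the four slice
   fractions, evaluated on 60 uniform fractions (1/60 … 1) and
   extrapolated linearly below the apical slice with a small positive
   floor. The surface is *not* forced to zero radius at the apex: doing
   so would collapse the contour over the whole bottom quarter of the
   ventricle (the region below the lowest annotated slice) and
   misrepresent untapered geometries badly — a no-taper cylinder would
   lose ~15% of its volume. Instead the apical closure is applied where
   it belongs physically, as the zero-area terminal point of the volume
   integral.
3. **Time**: a periodic cubic spline through the frames' phases,
   resampled to 60 uniform phases.

Every stage interpolates, so mesh values at anchor coordinates equal the
input radii (tested to 1e−6), the mesh is temporally periodic, and
refining the output resolution changes contour perimeters by <0.5%.
At least 8 frames are required; fewer cannot support a meaningful
periodic time spline.

## Kinematics

Strain is Lagrangian, referenced to end-diastole (phase 0):

* circumferential, per z level: closed polyline perimeter of the
  60-point contour, ε_C(t, z) = (P_t − P_0)/P_0;
* longitudinal, per rotation: 3D polyline length of the apex-to-base
  generatrix at fixed θ (using the per-frame apex/base axial positions),
  ε_L(t, θ) = (L_t − L_0)/L_0.

**Strain-rate windows.** Early/late systolic and diastolic strain rates
are reported as OLS slopes of strain versus time (seconds) over
half-windows: systole [0, ps] and diastole [ps, 1] are each split at
their midpoint. The window definition is a package choice — the field
reports these rates without a canonical window convention — and it is
the single most consequential convention in the metric table: early
diastolic strain rate is the metric most sensitive to temporal smoothing
and windowing, and it is exactly the quantity on which predicted and
ground-truth tables disagree most in our own comparisons.

**Peak systole** is located once, globally, as the phase of minimum
endocardial cavity volume (earliest sample on ties), so every curve
shares one phase landmark rather than each curve nominating its own.

**Volumes** are trapezoidal sums over z of the shoelace polygon area of
the endocardial contour, with the apex closure as an explicit zero-area
point at the apex; EDV is the volume at phase 0, PSV the minimum, SV and
EF follow. With 60-point contours the polygon underestimates a circle's
area by 0.18%, and the apex trapezoid contributes <1% for an untapered
wall — a no-taper cylinder reproduces π r² h within 2% (tested), and
ratio metrics such as EF are exact under uniform radial scaling.

**Metric table.** Per boundary, `metric_table()` reports peak strain
(signed extremum) plus the four rates at three circumferential levels
(basal z = 1.00, mid-LV 0.50, apical 0.25) and six rotations — 45 curve
metrics — plus the four global metrics, 49 rows. Including both
boundaries doubles the curve block. The table is deliberately
configurable because metric enumerations of this kind differ between
labs; no single count is canonical.

## The synthetic phantom

`generate_cohort()` emulates the features of murine 4DUS that matter for
the models, with exact ground truth:

* short-axis rings — a bright myocardial annulus (epicardium enclosing
  endocardium) over a darker blood pool and background;
* per-animal heart-size offsets — the end-diastolic endocardial radius
  is drawn per animal (default 1.5 ± 0.2 mm); this is the variation the
  assisted model exploits;
* smooth periodic contraction — radii follow
  r(t) = r_ED · (1 − a·g(t)) with a raised-cosine bump g (g(0) = 0,
  g(ps) = 1, C¹ everywhere including the wrap), peak systole at phase
  0.35 by default, ~25% peak endocardial contraction, and an epicardial
  amplitude scaled down so the wall thickens through systole;
* regional variation — each animal draws low-order harmonic
  perturbations of contraction amplitude, smooth in θ and z, so anchors
  move regularly rather than independently;
* an ellipsoid-like apex-to-base taper, with the epicardium keeping a
  finite apical cap;
* longitudinal shortening — the base moves toward the fixed apex
  (default 12% peak), exercising through-plane compensation and
  longitudinal strain;
* multiplicative Rayleigh-like speckle with configurable strength, and
  an attenuated angular shadow sector over the basal posterior septum
  (default 60° around 225°, basal quarter) emulating the sternum shadow
  that degrades real basal-septal contours;
* 30–40 frames per cycle territory (default 32; desk-scale tests use
  16–20) at a 500 bpm heart rate.

Defaults were chosen once, from typical adult-mouse anatomy (endocardial
radius ~1.5 mm, wall ~0.8 mm, LV length 6.5 mm, EF ~50%); the field of
view (image size × pixel spacing) must contain the largest plausible
heart, and the configuration validates this.

What the phantom does **not** model: ultrasound physics (point-spread
functions, depth-dependent attenuation, refraction), papillary muscles
(excluded from contours by convention), valve anatomy, ECG gating,
arrhythmia, and inter-observer annotation noise. Consequently, passing
tests demonstrate that the algorithms are implemented correctly and that
the model ordering holds under size offsets, speckle and shadow — they
do not certify performance on real animals, where boundary contrast,
annotation variability and pathology add error sources the phantom
lacks. Absolute R² values on the phantom are higher than any real cohort
would give.

A second generator, `generate_linear_cohort()`, produces cohorts drawn
*exactly* from the regression model family (low-rank images whose latent
scores linearly determine the radii). It is the reference for parameter
recovery — cross-validated R² must exceed 0.99 there, and test MSE is at
numerical-noise level — and, with `image_signal = "noise"` and
`radius_signal = "none"`, for the no-signal null where R² must sit near
zero.

## Evaluation harness

`mc_partition()` assigns whole animals to train/validation/test at
6:1:1 (floor(n/8) each to test and validation, remainder to train; 136
animals → 102/17/17), so frames of one animal never straddle splits.
`run_cross_validation()` repeats: refit PCA on training images, fit every
candidate k on training rows, select k by pooled validation MSE (ties to
the smallest k), evaluate per-anchor test MSE and R² (R² against the
test-set mean of each anchor) without refitting. Each iteration draws
its partition from `seed + iteration`, so any single iteration is
reproducible in isolation.

Model pairs are compared by two-sided paired t-tests on per-observation
squared errors within each (iteration, anchor) cell — the paired unit is
the (animal, frame) observation — and "significantly better" requires
both p < 0.05 and a smaller mean error, reported as a percent across
anchors and iterations per boundary. Zero-variance differences are
degenerate: p is 0 when the mean difference is nonzero, 1 otherwise,
with a flag. Truth-versus-predicted metric tables are compared by paired
t-tests across animals with plain Bonferroni scaling by the metric count
(the Dunn variant without step-down), flagged at adjusted p < 0.001.
One caveat worth stating: against noiseless phantom ground truth, tiny
but *systematic* interpolation and smoothing biases (shared across
animals) can reach significance even when the deviations are negligible
in magnitude — significance flags measure consistency, not size, of
disagreement.

## Problem sizes and numerical tolerances

The shipped tests and acceptance script use desk-scale conditions chosen
as the package's own study design: phantom cohorts of 12–24 animals,
16–20 frames per cycle, 40–48 px images at the full 6.4 mm field of
view, 10 stored slices; cross-validation with 10–20 iterations and k
grids {4, 8} (or the exact latent rank for linear-family cohorts); the
model-ordering experiment runs 20 replicates of a 24-animal, 20-iteration
cross-validation. Key tolerances: anchor interpolation exactness 1e−6;
OLS and PCA oracle agreement 1e−8; partition-of-unity 1e−12; cylinder
volume 2%; EF under uniform scaling 1%; mesh refinement stability 0.5%.

## Known limitations

* The z-interpolation extrapolates below the apical slice; strongly
  non-monotone apical geometries would be represented by their linear
  trend there. Volumes near the apex are correspondingly approximate.
* The mesh leaves the base open (no basal cap); volumes are integrated
  to the basal slice exactly.
* Strain-rate values depend on the half-window convention above; compare
  absolute rates across packages only after matching windows.
* The assisted model consumes a *true* annotation; annotation error is
  not modeled.
* `fit_boundary_model()` pools frames of all training animals per anchor
  — per-animal fits are not offered.
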