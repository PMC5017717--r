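---
title: "Two-stage deformable registration of liver CT: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage deformable registration of liver CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(liverreg)
```

## The registration problem

CT-guided percutaneous ablation confronts the radiologist with three
images of the same liver in three states: the diagnostic
contrast-enhanced CT `D` in which liver and tumor are segmented; the
full intra-operative CT `F` acquired at the start of the intervention,
usually without contrast agent and often with the patient rotated about
the cranio-caudal axis for needle access; and thin needle-check slabs
`N` acquired during needle advancement. The package estimates spatial
transforms `T_DF` and `T_DN` that carry the tumor annotation from `D`
into `F` and `N`.

All geometry is expressed in world millimetres: voxel indices are
0-based, denote voxel centers, and map to world coordinates through
`origin + direction %*% (spacing * index)`. Every transform maps
fixed-image world coordinates into the moving image (the resampling
convention), so the same object that resamples `D` onto `F` also
transforms `F`-image landmarks toward `D` for landmark-distance
evaluation.

## Transformation model

Non-rigid deformation is a cubic B-spline free-form deformation,
`T(x) = x + u(x)`, with `u` parameterized by 3-vector displacements `mu`
of a regular control grid and evaluated as the 4x4x4 tensor-product
B-spline sum. Cubic B-splines have linear precision, which
`embed_affine()` exploits to represent any affine map exactly; the test
suite uses this to validate derivatives and the rigidity penalty in
closed form. Control grids always extend two spacings beyond the
fixed-image bounding box so that every point of the image has full
support.

The multiresolution schedule uses grid spacings of 80, 40, 20 and 10 mm.
The estimate is carried between resolutions by exact dyadic B-spline
subdivision (two-scale masks [1 6 1]/8 and [4 4]/8), so no accuracy is
lost at level changes; non-dyadic refinements fall back to a cubic
nodal-interpolation fit that is exact away from the grid boundary. An
image pyramid accompanies the grid schedule with downsampling factors
(8, 4, 2, 1) and Gaussian smoothing of sigma = factor/2 voxels — one
image level per grid level; the pyramid factor is clamped per axis so at
least four voxels remain (relevant for thin needle slabs). When an
initial transform is present the composition is `T(x) = init(x + u(x))`;
with a rigid `init` the rigidity conditions of the total transform equal
those of the FFD component, which is why the penalty below is evaluated
on the FFD alone.

## Similarity: binned mutual information

The registration minimizes `-MI + alpha * P_rigid`. MI is computed from
a joint histogram of 32 x 32 bins (a standard choice for CT that remains
well-populated with 2000 samples; the bin count is not critical), in
natural-log units. At every iteration a fresh set of 2000 points is
drawn uniformly from the voxels of the fixed mask — masks in this
workflow are rough contours drawn slightly larger than the liver, which
deliberately include the liver boundary and nearby tissue, where most of
the alignment information lives.

Implementation choices that matter:

* **Parzen windows.** Both intensity axes use cubic B-spline windows,
  making the histogram — and hence MI — differentiable in `mu` (only the
  moving axis enters the gradient; the fixed intensities never depend on
  the parameters). A smooth window on the *fixed* axis as well is
  deliberate: with a box window the within-bin Parzen pull does not
  cancel across samples and the gradient acquires a bin-center
  attraction artifact, so a perfect alignment would not be a stationary
  point of the sampled metric. Each axis is padded by two bins so the
  4-bin window support never leaves the histogram and the window weights
  always sum to one.
* **Bin ranges.** Intensity ranges are fixed per resolution level from
  the 0.2/99.8 percentiles of the masked fixed image and of the moving
  image (inside its own liver mask when available). Percentiles rather
  than extrema: a handful of hyperdense voxels — surgical clips, the
  ablation needle at ~3000 HU — would otherwise compress all soft-tissue
  contrast into one bin and destroy the metric.
* **Out-of-domain samples** are dropped; if more than half the samples
  leave the moving image the registration aborts with a
  gross-misalignment error instead of optimizing a meaningless
  histogram.
* **Gradient.** `d(-MI)/d mu` is assembled by the chain rule through the
  Parzen window derivative, the moving image's trilinear intensity
  gradient, the spatial Jacobian of any initial transform, and the
  B-spline basis support. Only control points with samples in their
  support receive nonzero entries. The analytic gradient is validated
  against central finite differences (shared sample set, relative error
  below 1e-2) in the test suite.

## Local rigidity penalty

User-guided refinement marks mis-registered regions with seed points.
Each seed voxel is dilated by a cube of 1 x 1 x 1 cm (rounded up to an
odd voxel count per axis) and the union forms the coefficient field
`c(x)` on the diagnostic image; a 5 mm Gaussian feather (doubled and
clamped to [0, 1], so seed regions keep c = 1) smooths the transition
between locally-rigid and free zones. Feather 0 reproduces a binary
mask; graded and binary masks are both supported.

The penalty is the c-weighted mean over evaluation points of
`c_AC * sum(AC^2) + c_OC * sum(OC^2) + c_PC * PC^2` with AC the
second-derivative tensor of the transform, `OC = J'J - I` and
`PC = det(J) - 1`; all three vanish iff the local motion is rigid, and
`c` is evaluated at the transformed location so the mask follows the
anatomy it was drawn on. Default weights c_AC = 100, c_OC = 1,
c_PC = 2 with per-resolution overall weights (0.1, 0.1, 0.1, 4): the
penalty binds strongly only at the finest grid, where implausible
deformations arise. Evaluation points are the control-grid nodes inside
the fixed image — the cost is then linear in the number of control
points and all derivatives are analytic; at coarse levels where no node
falls inside a small seed region, the penalty is simply inactive for
that level. The gradient freezes `c` (it is not differentiated through
the transform), a standard approximation documented here because it
slightly biases the penalty gradient near steep feather slopes.

## Optimizer

Stochastic gradient descent with the Robbins–Monro gain
`gamma_t = a / (A + t)^0.602`, A = 50, for exactly 500 iterations per
resolution (no early stopping — iteration count is the convergence
budget). The numerator `a` is auto-scaled so the first step moves the
largest control-point displacement by a quarter of the current grid
spacing, making behavior resolution-independent. Two safeguards:
per-iteration steps are capped at that same target (the rigidity penalty
is quartic in `mu`, so gradients can outgrow a gain calibrated at the
start of a level), and non-finite costs or gradients abort with the
trace attached. Identical inputs and master seed give bit-identical
results; every sample draw derives its stream from the master seed, the
level and the iteration index.

## The synthetic phantom

No clinical data accompanies the package, so validation runs on
synthetic deformable CT phantoms with exact ground truth. The phantom
emulates, in order of importance to the method:

* a liver of about 100 HU with an **asymmetric, wedge-tapered** boundary
  (a pure ellipsoid is nearly invariant to z-rotation and would make the
  rotation pre-alignment appear useless, which is not how real livers
  behave), smooth boundary roughness, and contrast-enhanced vessels at
  180 HU whose branch and mid points provide 10–15 landmarks;
* a hypodense tumor (default 60 HU, 12 mm radius) inside the liver;
* soft-tissue background at 40 HU, organ blobs, air at −1000 HU, and
  additive Gaussian noise (sigma 10 HU);
* **rough registration masks**: the liver dilated by 8 mm, mirroring the
  clinically drawn contours "slightly larger than the liver"; the exact
  masks are reserved for evaluation;
* the intra-operative state: a rigid pose change (default 30° about the
  liver center of mass plus a small translation) followed by a smooth
  random FFD (15 mm amplitude on a 50 mm grid — deliberately a
  *different* parameterization than any registration grid, to avoid an
  inverse crime), with folding excluded by a positive-Jacobian check;
* contrast removal: in non-enhanced mode vessels drop to 80 HU — subtly
  hypodense against 100 HU parenchyma, as unenhanced blood actually is,
  rather than invisible. The 100-HU change in vessel intensity between D
  and F still defeats intensity-difference metrics, so MI is genuinely
  exercised;
* a needle slab: a few axial slices cropped after a small rigid drift,
  with a 1.5 mm-radius, 3000 HU needle; optionally a small in-plane
  deformation as residual breathing motion between F and N.

Ground-truth landmark positions in F are obtained by exact fixed-point
inversion of the truth transform, so the landmark distance of any
registration is a pure error measure (the truth itself scores 0 to
machine precision).

What the phantom does **not** emulate: CT texture, independently moving
neighboring organs, sliding at the liver surface, breathing artifacts,
and segmentation/annotation error. Registration accuracies on the
phantom are therefore substantially better than clinical figures —
stage-1 surface distances are sub-millimetre where clinical studies
report several millimetres — and passing tests demonstrate correctness
of the machinery and the *directions* of the clinical findings (rotation
degrades registration; seeded rigidity repairs locally wrong
deformations; the final stage-2 registration improves tumor targeting
over mere transform concatenation), not clinical error magnitudes.

## Validation problem sizes

The tests and the acceptance script run phantoms of 96 x 96 x 64 voxels
at 2 x 2 x 3 mm (the anisotropic clinical spacing regime at a desk-scale
matrix) with 80 iterations per resolution and 150 for the rigid stage —
enough for convergence at this problem size, as the per-level cost
traces confirm; the package default remains the clinical 500. The
stage-2 comparison phantom uses an 11-slice slab with an 8 mm residual
in-plane deformation at 25 mm scale (shallow-breathing regime). On the
thin slab the sampled-MI optimum sits about 2 mm from the truth (the
aperture problem of a limited field of view), so the final non-rigid
stage is judged on the tumor-targeting error, which it consistently
improves, rather than on a boundary overlap that concatenation already
saturates on this clean phantom.

## Numerical and degenerate-input choices

* Resampling outside the source image yields −1000 HU (air).
* Interpolation: linear for images (with "nearest" for masks and
  annotations, and Keys cubic available); surfaces for the mean surface
  distance come from a 6-connected one-voxel erosion (26-connectivity is
  available), distances between voxel centers in world mm.
* An FFD queried outside its fully-supported interior raises an error by
  default; extrapolation-by-zero-displacement is explicit opt-in
  (`extrapolate = TRUE`), used internally where samples may leave the
  grid margin.
* Empty masks, mismatched geometries, unpaired landmark sets, slabs
  thinner than 3 slices, and all-zero coefficient masks are rejected
  with specific errors; the degenerate-mask condition is classed so the
  optimizer can distinguish "no penalty support at this level" from user
  error.
* Transform JSON serialization round-trips at full double precision;
  unknown format versions are rejected.

## Known limitations

* The rigid z-rotation pre-alignment is an input (as in the clinical
  workflow, where it is set manually); it is not estimated.
* The stage-2 slab registration inherits the aperture problem of thin
  slabs: out-of-plane motion is weakly constrained, and boundary-overlap
  metrics on slabs should be read with that in mind.
* The frozen-coefficient rigidity gradient is an approximation; it is
  exact for binary masks away from the feather band.
* MI is implemented with the standard logarithmic definition; normalized
  MI variants and cross-correlation metrics are out of scope.
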