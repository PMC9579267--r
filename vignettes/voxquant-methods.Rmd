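---
title: "Methods: models, parameters and numerical choices in voxquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices in voxquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

voxquant is a headless toolkit for quantitative multimodality
nuclear-medicine image analysis. This vignette documents the models it
implements, the parameters that matter, the numerical choices made where the
design was genuinely open, and what the synthetic phantoms do and do not
show about real data.

## Coordinate model

All geometry lives in the DICOM patient frame: LPS (+x left, +y posterior,
+z superior), millimetres. Voxel indices are 0-based and the grid origin is
the *center* of voxel (0,0,0), matching DICOM ImagePositionPatient. A
`grid_geometry` is (dims, spacing, origin, direction) with an orthonormal
direction matrix; `voxel_to_world()` is
`origin + direction %*% (spacing * index)` and is exactly invertible, which
the tests check to 1e-9 mm.

Patient-position codes (HFS, FFS, HFP, FFP, and the four decubitus codes)
are modeled as signed permutation matrices mapping scanner axes to patient
axes. Correcting a mis-declared position applies
`t(P_declared) %*% P_actual` to the voxel axes — a pure permutation/flip,
never an interpolation — and keeps the grid center fixed in patient space so
the corrected series stays inside the original field of view.

## Interpolation and resampling

Five modes are offered under their viewer names: `nearest`, `linear`
(trilinear), `cubic` (tricubic Catmull–Rom), and the slice-wise `bilinear` /
`bicubic`, which interpolate within slices and take the nearest slice along
k. The 2-D/3-D split is a convention choice: the mode names are plural in
common viewers without a published definition, and slice-wise behavior
matches how such viewers treat thick-slice series. Catmull–Rom reproduces
linear fields exactly and interpolates (rather than approximates) sample
values; at grid borders taps are clamped (replicate) so identity resampling
stays exact. Out-of-support samples take a value-kind-dependent fill: −1000
for HU (air), 0 otherwise. Trilinear resampling reproduces globally affine
intensity fields to 1e-6, which is the test oracle for the thick-to-thin
slice workflow.

## Registration

`register_volumes()` estimates a rigid, similarity (rotation × uniform
scale), or affine transform mapping reference-space points into the moving
volume (the resampling convention, so the result feeds directly into
`apply_transform()`). The metric is mean squared error for same-modality
pairs and negative mutual information (32×32 joint histogram) across
modalities — the sources describe registration only by its transform models,
so the metric/optimizer stack is this package's own design. Out-of-support
moving samples take the background fill rather than being dropped: dropping
them biases the sampled mean discontinuously at the support boundary, which
traps descent methods.

Optimization is deterministic and derivative-free:

1. integer-voxel translation from the FFT cross-correlation peak (on the
   absolute correlation, so anticorrelated cross-modality content still
   aligns);
2. translation-only refinement with multi-start — the sampled MSE of
   linearly interpolated volumes ripples at grid-commensurate alignments,
   and probing a half/full-voxel neighborhood of the correlation peak
   escapes those traps;
3. Nelder–Mead over the full parameter set at a coarse (1-in-4 sample) and a
   fine level, with a restart per level and, for rigid/similarity,
   ±0.02 rad perturbation restarts of the rotation parameters (adjacent
   ripple minima sit roughly a degree apart);
4. a coordinate-wise golden-section polish, which tolerates the derivative
   kinks of linear interpolation that stall simplex steps near the optimum.

Parameter scaling treats translations in mm and rotations/log-scale in
~0.02–0.1 rad units. On the four-blob phantom used in the tests the
recovered transform is accurate to well under half a voxel in translation
and under a degree in rotation; accuracy degrades on nearly symmetric
content (rotation about a blob axis is weakly constrained), which is a
property of the data, not the optimizer.

## Image arithmetic, geometric mean, filtering, convolution

Voxelwise operators require a shared grid (resample first; the error message
says so). Division by zero yields 0 and counts the affected voxels.

The conjugate-view geometric mean flips the anterior view left–right,
optionally applies an integer-pixel translation found by cross-correlation
(center-of-rotation correction; translation-only by default), clamps
negatives to zero and returns `sqrt(ANT_flipped * POST)`.

Gaussian post-filters are specified by FWHM in mm, converted per axis by the
voxel spacing (`sigma = FWHM / 2.355`), kernel truncated at 4 sigma and
normalized to unit sum; `2D` mode filters within slices only.

`convolve_volume()` first resamples the kernel from its native spacing onto
the image spacing. Under `preserve_sum` (the right contract for dose
kernels) the resampled kernel is rescaled to keep its total weight, so
energy bookkeeping survives grid changes. Convolution is zero-padded linear
convolution — conservative for count data — with an FFT path (default) and a
direct shift-and-add path that the tests require to agree to 1e-6. A masked
convolution zeroes the input outside the mask first and does *not*
renormalize at mask edges.

## Segmentation

Threshold predicates (`min_to_value`, `value_to_max`, `between`) are
inclusive at their bounds, so "value to max" contains the maximum.
Constraints restrict both the predicate and, for `percent_of_max` units, the
reference maximum to the allowed region. Connected components use
26-connectivity by default, built as a voxel adjacency graph and labeled
with igraph.

Edge detection is slice-wise by default (the operators are 2-D); gradients
use replicate padding so flat regions and image borders produce no spurious
edges, and magnitudes below 1e-9 of the data range are flushed to zero to
kill FFT roundoff. Canny uses sigma = 1 voxel smoothing, non-maximum
suppression over four quantized directions, and hysteresis with thresholds
at the 70th/90th percentiles of the nonzero gradient magnitudes;
"Approx-Canny" — named but never defined in viewer documentation — is
implemented as Canny without the hysteresis step (single high threshold).

Lung segmentation (no published algorithm; this is the package's own): HU <
−320 threshold (generous enough to include bronchi), remove components
touching the volume border (exterior air), keep the two largest components,
morphological closing with a 3 mm ball to reincorporate vessels, a hard
guard that no voxel ≥ −300 HU ever enters a lung mask, and — when the lungs
fuse into one component — erosion until separation followed by competitive
geodesic dilation (watershed-by-dilation) to split them. Laterality is
assigned by centroid: patient-left is +x in LPS.

## Total tumor burden

The pipeline's defaults are the published workflow values: region growing at
**10%** (of the global maximum within non-excluded space — the reference
value is not stated in the workflow description, so global-max was chosen
and is user-adjustable), per-object segmentation at **42%** of the object's
maximum voxel (SUVmax rather than SUVpeak, another open reading), additional
peaks admitted at **20%** of the object maximum and segmented at 42% of
their own local maxima, and a strict **0.3 ml** minimum VOI volume
("exceed", so exactly 0.3 ml is removed).

Secondary peaks are found iteratively on the residual (object minus
already-segmented regions), highest first. A residual candidate must be a
26-neighborhood local maximum *with respect to the whole object*, not just
the residual: otherwise voxels on the rim of an already-removed region
(values just below 42% of the peak but above 20%) masquerade as local maxima
and spawn spurious VOIs. Because each region grows only within the residual,
VOIs are automatically pairwise disjoint subsets of their object, and
overlap resolution never arises as a separate step; the flip side is that a
secondary region can collect the primary lesion's residual skirt (voxels
between the secondary and primary thresholds), inflating its volume relative
to an isolated lesion of the same peak. Review order is superior
to inferior by centroid S coordinate; deletion removes a VOI from the global
mask and records its id, and deleting an unknown id is an error.

Everything in percent mode is ratio-based, so the output is invariant under
global intensity rescaling — asserted in the tests by multiplying the PET
by 7.

For an isolated Gaussian lesion (peak M, width sigma), the 42% region is
analytically a ball of radius `sigma * sqrt(2 * ln(1/0.42))`; at sigma =
6 mm on a 1 mm grid the measured VOI volume agrees with the analytic volume
to within 5% (about 1.7% when the lesion center coincides with a voxel
center, which is how the test grid is laid out — an even-dimensioned grid
puts the peak between voxels and costs another ~3% through the lower
realized maximum).

## Dosimetry

Tissue assignment maps HU ranges (default: lung < −120 < soft tissue < 120 <
bone, densities 0.26 / 1.00 / 1.85 g/ml) to labels, with VOI overrides
taking precedence and out-of-range voxels falling back to a declared default
with a warning count. Dose rate is region-wise kernel convolution: per
tissue, the activity masked to that tissue is convolved with that tissue's
kernel (resampled to the image grid, sum-preserving), and contributions are
summed. This composition rule is explicit, linear, and testable; it is an
approximation — true heterogeneous transport is out of scope. The optional
density correction divides each voxel's dose by its local density relative
to water, the simplest reading of "CT density corrections"; it is documented
as approximate. Kernel units are a contract: Gy/h per Bq/ml per voxel after
grid resampling. No decay data are hardcoded — radionuclide specificity
(e.g. Y-90) lives entirely in the user-supplied kernel file.

DVHs are cumulative: the fraction of VOI volume receiving at least each dose
level over 200 equal-width bins (default) from zero to the VOI maximum. The
curve starts at 1, never increases, and its trapezoid integral reproduces
the voxelwise mean dose within binning error.

## Fusion and isosurfaces

Window/level normalization is `clamp((v - (level - window/2)) / window, 0, 1)`.
Blending is sequential: each overlay contributes
`out = (1 - alpha*m)*out + alpha*m*color(m)`, so order matters by contract
(overlays with disjoint supports commute, which is also asserted). The
three-tracer RGB fusion assigns each tracer a primary channel over a
grayscale CT; tracers whose normalized intensity reaches their inclusion
threshold are "included", and the included channel(s) of maximal intensity
are set to full saturation — the color burst. Ties saturate all tied
channels, reproducing the Venn-overlap colors (red+green → yellow). The
burst *replaces* the blended value at those voxels (replacement versus
addition is unspecified in viewer descriptions; replacement keeps channels
in [0,1] by construction). Voxels with no tracer included show the CT alone.

Isosurfaces use marching tetrahedra on a 6-tet cube decomposition, with
vertices merged by canonical global edge keys so closed level sets yield
watertight 2-manifold meshes (Euler characteristic 2 for sphere topology,
asserted). Values exactly equal to the level are nudged by 1e-9 of the data
range so no vertex degenerates onto a grid point. Binary (two-valued)
volumes are antialiased with a small Gaussian (sigma 0.7 voxel) before
extraction: raw marching on 0/1 data inflates sphere surface area by roughly
9% through staircase artifacts, while with antialiasing the error is under
1% (area) and ~2.5% (enclosed volume) for a 10 mm sphere on a 1 mm grid —
the sigma was validated on that analytic sphere before the tests were
frozen. Mesh export is binary STL in mm; bitmap stacks rasterize the mesh
interior plane by plane (even-odd rule against the triangle/plane
intersection segments) at a user slice thickness, with planes centered in
the z extent so the first and last are not degenerate tangent cuts.

## DICOM I/O

No DICOM library is part of the R stack this package targets, so it carries
a minimal, auditable explicit-VR little-endian codec: enough of the standard
to write and re-read image series (secondary-capture-style tag set plus full
geometry, modality, rescale and radiopharmaceutical tags) and RT structure
sets. Vendor private elements are tolerated (carried as raw bytes) on read
and never written. Slices sort by the projection of ImagePositionPatient on
the slice normal; nonuniform slice spacing beyond 1% of the mean warns and
falls back to the mean. Voxels are quantized to 16 bits with a per-series
rescale slope/intercept, so write→read round-trips are exact to one rescale
quantum. SUV conversion is body-weight SUV with the injected dose
decay-corrected from injection time to series time; other SUV variants (lean
mass, BSA) are out of scope.

Mask→contour conversion extracts iso-level 0.5 contours per slice (holes
become separate rings); contour→mask rasterization is even-odd with voxel
centers, so a convex mask round-trips its volume essentially exactly and
well within the 2% the tests require.

## Phantoms: what passing tests show

Solid shapes voxelize by the center-inside rule with no antialiasing, so
brute-force oracles are exact; overlapping solid shapes are last-writer-wins.
Gaussian blobs *add* (activity is additive), so a blob's realized maximum
slightly exceeds its nominal peak when blobs overlap — at the default
multipeak separation (20 mm, sigma 6 mm) the cross-contamination is under
1%. All randomness (noise) is seeded through the spec.

The phantoms emulate geometry, value semantics and the parameter regimes of
the workflows (SUV levels, HU classes, lesion sizes around the 0.3 ml
filter). They do not emulate scanner physics: no PSF, scatter, attenuation,
reconstruction noise texture, or respiratory motion. Passing tests therefore
demonstrate that the *algorithms implement their definitions* and recover
analytic ground truth under ideal sampling — not that clinical accuracy at a
given noise level is guaranteed. Problem sizes in the test suite (64³ grids
and below, 32³ for registration) were chosen so the full suite documents the
behavior at interactive scale; all quantities converge with grid refinement
and the convergence itself is asserted where it is the point (voxelization
error, 42% volume recovery).

## Known limitations

- Registration is intensity-based and local: it needs overlapping support
  and a sensible initialization (provided by cross-correlation), and it does
  not do deformable alignment.
- The DICOM codec reads only explicit-VR little-endian files (which is also
  the only form it writes); compressed transfer syntaxes are rejected.
- Region-wise dose convolution ignores cross-boundary transport differences;
  density correction is a first-order scaling.
- "Spatially variant" kernels are realized as region-wise kernels (one per
  mask), not per-voxel varying kernels.
- Expression arithmetic is bounded to the four operators plus unary
  sqrt/log/exp.
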