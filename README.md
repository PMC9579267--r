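# voxquant

Quantitative voxel analysis for nuclear-medicine imaging, as a headless,
scriptable R toolkit. It covers the computational core of a multimodality
molecular-imaging workstation — everything except the interactive display:

- **I/O** — DICOM image series (CT, PET, NM, MR, ...) and DICOM RT structure
  sets, read and written with a built-in explicit-VR little-endian codec;
  binary STL meshes, 8-bit BMP slice stacks for 3-D printing, CSV statistics.
- **Geometry** — resampling between grids (nearest / linear / cubic /
  bilinear / bicubic), patient-orientation correction (HFS/FFS/HFP/FFP and
  decubitus codes), oblique reslicing, maximum intensity projection, and
  rigid / similarity / affine intensity-based registration.
- **Arithmetic** — voxelwise operators, conjugate-view geometric mean
  `sqrt(ANT_flipped x POST)`, 2-D/3-D Gaussian post-filters, and convolution
  with user-defined kernels that carry their own grid spacing.
- **Segmentation** — inclusive min/max/between thresholds with inside/outside
  constraint regions, voxel replacement (confounder removal,
  de-identification), Sobel / Prewitt / Canny / Approx-Canny edge detection,
  left/right lung segmentation, connected-object labeling, VOI aggregation.
- **Total tumor burden** — the three-stage pipeline: 3-D region growing at
  10% of the global maximum detects candidate lesions; each object is
  segmented at 42% of its maximum, with additional peaks admitted at 20% of
  the object maximum and segmented at 42% of their own local maxima; VOIs
  must exceed 0.3 ml; sequential superior-to-inferior review with deletion.
- **Dosimetry** — tissue assignment from CT Hounsfield ranges with VOI
  overrides, dose-rate estimation by tissue-specific dose point-kernel
  convolution, cumulative dose-volume histograms.
- **Fusion** — per-layer window/level + colormap + alpha blending, the
  three-tracer RGB fusion with a color burst on the dominant tracer(s), and
  marching-tetrahedra isosurface extraction.
- **Phantoms** — every test input is generated programmatically with
  analytic ground truth (spheres, ellipsoids, boxes, Gaussian lesions,
  a thorax CT, multi-peak PET, conjugate planar pairs).

## The statistics it reports

For a volume of interest the toolkit reports volume (ml), total, mean, min,
max, peak (SUVpeak convention: mean over a 1 ml sphere at the hottest
voxel), population SD, and — for SUV volumes — total lesion glycolysis
`TLG = mean SUV x volume`. Whole-body burden summaries are the total
metabolic volume `TMV = sum of VOI volumes` and `TLG = sum of per-VOI TLG`.
SUV is body-weight SUV: `SUVbw = concentration / (decayed dose / weight)`.

## Worked example

```r
library(voxquant)

# a PET phantom with two merged lesions: peaks SUV 10 and 5, 20 mm apart
pet <- make_multipeak_pet(peaks = c(10, 5), separation_mm = 20, sigma_mm = 6)

res <- total_tumor_burden(pet)     # 10% grow, 42% local, 20% secondary, 0.3 ml
print(res)
#> burden_result: 2 VOIs (1 candidate objects, 0 deleted)
#> VOI 'VOI_01': 2.304 ml | mean 5.96 | min 4.063 | max 9.624 | peak 7.154 | sd 1.462
#>   TLG: 13.73
#> VOI 'VOI_02': 5.696 ml | mean 2.94 | min 2.045 | max 4.861 | peak 3.663 | sd 0.6364
#>   TLG: 16.75

burden_report(res, pet)            # per-VOI rows plus the TOTAL row
write_rtstruct(res$vois, pet$geometry, "burden.dcm")   # DICOM RT structure set
```

The single candidate object is split into two VOIs: the 5-peak lesion
exceeds 20% of the object maximum (9.62 on this grid), so it is segmented
separately at 42% of its own local maximum (threshold 2.05 rather than
4.06); its region also collects the primary lesion's residual skirt between
those two thresholds, hence its larger volume. Multiplying the PET by any
constant changes none of the masks.

A batch interface mirrors each workflow
(`inst/cli/voxquant <subcommand> ...`): `phantom`, `resample`, `reorient`,
`register`, `arith`, `geomean`, `gauss`, `convolve`, `segment`, `lungs`,
`edges`, `burden`, `dose`, `dvh`, `isosurface`, `mip`, `fuse`, `stats`.

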