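Package: voxquant
Title: Quantitative Voxel Analysis for Nuclear-Medicine Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless, scriptable toolkit for quantitative multimodality
    nuclear-medicine image analysis: DICOM image-series and RT-structure-set
    input/output, resampling, patient-orientation correction, oblique
    reslicing, rigid/similarity/affine registration, maximum intensity
    projection, image arithmetic with conjugate-view geometric mean, Gaussian
    post-filtering and convolution with user-defined dose kernels,
    constrained threshold segmentation, lung segmentation, edge detection, a
    multi-stage total-tumor-burden pipeline (region growing, per-object
    percent-of-peak segmentation, minimum-volume filtering), voxel
    dose-kernel dosimetry with dose-volume histograms, multi-tracer RGB
    fusion, and isosurface extraction with STL and bitmap-stack export for
    3-D printing. All test fixtures are generated programmatically by a
    phantom module.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    grDevices,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
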