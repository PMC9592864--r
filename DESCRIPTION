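Package: hexIHC
Title: Automated Whole-Slide Immunohistochemistry Quantification with
    Hexagonal Stereology Grids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automated quantification of DAB immunostaining within
    the epithelial compartment of whole-slide images. Detects stained
    pixels in the Ohta color space with Gaussian-mixture pixel
    classification, segments epithelium by windowed-Fourier low-pass
    filtering with moment-preserving thresholding and morphological
    opening, calibrates and quality-controls both detectors against
    expert stereology point grids, measures per-hexagon transmittance of
    staining restricted to epithelium, classifies hexagons into
    low/medium/high intensity classes by deterministic one-dimensional
    Gaussian mixture thresholds, and summarises each case either by
    hexagon class counts or by a PCA composite score built from the
    first three moments of the transmittance distribution. Includes a
    synthetic slide-phantom generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    tiff,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
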