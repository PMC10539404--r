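Package: dffoct
Title: Dynamic Full-Field OCT Contrast Metrics, Mosaicking and Acquisition Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for processing dynamic full-field optical coherence tomography
    (D-FFOCT) image time series without instrument access. Provides a synthetic
    phase-diffusion signal model for interferometric pixel fluctuations, per-pixel
    power-spectral-density metrics (mean frequency, frequency spread, fluctuation
    amplitude) with temporal binning and hue-saturation-brightness rendering, a
    translation-only mosaic stitcher with normalized cross-correlation registration
    and feathered blending, a histogram two-peak thresholding and area-based cell
    counting pipeline for stained nuclei stacks, and a discrete-event model of the
    pipelined acquisition-transfer-processing-saving workflow with closed-form
    throughput expressions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png,
    yaml
Config/testthat/edition: 3
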