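Package: rgcsc
Title: Spatial-Contrast Encoding Models for Retinal Ganglion Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling spike-count responses of retinal ganglion
    cells to flashed natural images. Implements receptive-field estimation
    from spatiotemporal white noise (spike-triggered average, singular-value
    decomposition, two-dimensional Gaussian fits), the two receptive-field
    image statistics mean intensity (I_mean) and local spatial contrast
    (LSC), the classical linear-nonlinear (LN) spike-count model and its
    spatial-contrast (SC) extension with a softplus output nonlinearity,
    a paired-difference analysis that isolates spatial-contrast effects
    from mean-intensity effects, a smoothing-scale analysis that estimates
    the spatial scale of nonlinear integration, response-quality metrics
    (Fano factors, polarity classification, inclusion filters, functional
    clustering), and a synthetic-data generator with ground-truth linear
    and rectified-subunit model cells for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    tiff,
    yaml,
    optparse
Config/testthat/edition: 3
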