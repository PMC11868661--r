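Package: octcorrect
Title: Depth-Dependent Correction of OCT A-Scans via Basis-Function Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the combined confocal and sensitivity fall-off envelope
    g(z) of a spectral-domain optical coherence tomography (OCT) system from
    two or more vertically shifted A-scans or B-scans of the same sample.
    The dB-scale log-ratio of the shifted scans cancels the sample term and
    isolates g, which is modelled as a linear combination of Chebyshev
    polynomials and solved by singular-value-decomposition least squares,
    with design-matrix conditioning diagnostics, multi-depth and multi-lateral
    extensions, and a moving-window laterally resolved variant. Includes the
    classical two-parameter confocal "Ratio Fit" baseline, a layered-phantom
    simulator with speckle and shot noise, B-scan preprocessing (debiasing,
    Gaussian smoothing), corrected-scan similarity metrics, and per-layer and
    depth-resolved attenuation-coefficient extraction under a single-scattering
    Beer-Lambert model.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
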