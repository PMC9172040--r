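Package: saxsdr
Title: Azimuthal Integration and Online Reduction of 2D Scattering Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces 2D small-angle X-ray scattering (SAXS) detector frames to
    one-dimensional intensity curves with Poisson counting-statistics error
    bands. Supports tilted-detector geometry in the FIT2D angle convention,
    anti-aliased radial rebinning through a sparse pixel-to-bin weighting
    matrix, FIT2D .msk and image-file pixel masks, horizontal and vertical
    detector-coordinate line cuts for grazing-incidence (GISAXS) monitoring,
    per-image scalar classifiers (integral intensity, Porod invariant,
    correlation length) with a queryable time history, and a watch-folder or
    event-fed processing queue with a worker pool for online beamline
    operation. Includes a synthetic-frame generator (flat fields, rings,
    sphere form factors, Poisson noise) so the full pipeline is testable
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    methods,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    pracma,
    rlang,
    tiff,
    png,
    parallel,
    tools,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
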