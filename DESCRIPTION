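Package: junctionmech
Title: Quantitative Methods for Junctional Mechanobiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for epithelial junctional mechanobiology
    experiments. Implements Sneddon conical-indenter fitting of atomic force
    microscopy force-indentation curves with baseline correction, contact-point
    detection and goodness-of-fit filtering; ratiometric FRET tension-sensor
    quantification from three-channel images with spectral bleed-through
    correction and linescan profiling; residue centre-of-geometry contact
    analysis of peptide-domain complexes with hydropathy classification and
    water-contact counting; a one-dimensional weighted-histogram (WHAM)
    free-energy estimator for umbrella-sampling windows with Bayesian-bootstrap
    errors and binding-energy extraction; cell-shape morphometry, monolayer
    hole quantification and the accompanying nonparametric group statistics.
    Every input class has a seeded synthetic generator with known ground truth
    so each pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    withr,
    stats,
    utils,
    tools,
    bio3d,
    tiff,
    readr,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
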