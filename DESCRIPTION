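Package: microfire
Title: Microcharcoal Quantification and Paleofire Reconstruction from
    Marine Sediment Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for reconstructing past biomass burning from
    microcharcoal preserved in deep-sea sediment cores. Detects and
    classifies opaque angular charcoal particles in transmitted-light
    micrographs, converts pixel counts to the CCsurf proxy (microcharcoal
    surface area per gram of dry sediment), builds piecewise-linear
    age-depth models from dated control points, and stratifies the fire
    proxy by Greenland Interstadial/Stadial climatic phases to quantify
    the logarithmic coupling between fuel load (pollen-derived biomass
    indices) and fire regime. Includes synthetic-data generators for
    micrographs with known particle ground truth and for core records
    with known phase structure, so the whole pipeline is testable without
    access to original core material.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
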