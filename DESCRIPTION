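Package: electrogenetics
Title: Modelling and Analysis Toolkit for Bacterial Electrogenetic Devices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative machinery for electrode-actuated bacterial gene
    circuits: bulk-electrolysis coulometry of the ferri/ferrocyanide couple
    (Nernst endpoints, Faraday charge accounting, first-order interconversion
    kinetics with cell-mediated re-reduction), charge-dependent reporter
    expression with ssrA-tag degradation and deconvolution of cumulative
    protein synthesis from fluorescence time series, a bacterial motility
    video tracker (Otsu segmentation, nearest-neighbour linking, drift and
    stuck-cell handling, velocity statistics and origin-translated trajectory
    roses), flow-cytometry population summarisation, and seeded synthetic-data
    generators with ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
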