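Package: gomech
Title: Quantitative Analysis of Graphene-Oxide Effects on Cell Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for the quantitative readouts used to study
    how graphene-oxide nanosheets alter cancer-cell mechanics: Hertz-model
    fitting of AFM force-distance curves to extract Young's modulus,
    block-wise nematic order-parameter analysis of actin fluorescence
    images, single-cell migration track statistics from microfluidic
    assays, and coarse-grained graphene-oxide/actin trajectory observables
    (centre-of-mass distances, native contacts, nonbonded energies and 2D
    free-energy landscapes).  Seeded synthetic-data generators produce
    every input with recorded ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
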