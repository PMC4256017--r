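Package: dcispotts
Title: Cellular Potts Simulation of Ductal Carcinoma In Situ Morphologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional multi-cell lattice (cellular Potts) model of
    ductal carcinoma in situ (DCIS) in the mammary duct. Metropolis
    pixel-copy dynamics act on an effective energy combining differential
    adhesion, volume and surface constraints, and contractile spring links
    between neighbouring cells' centers of mass. A biological event layer
    adds scheduled mitosis with configurable division axes, crowding-gated
    stochastic apoptosis, and distance-gated necrosis. The package builds
    circular, cylindrical and bifurcating duct tissues, classifies
    simulated snapshots into the four histological DCIS morphologies
    (micropapillary, cribriform, solid, comedo), quantifies invasion
    through the myoepithelial layer by tissue region, and provides a
    harness for seeded replicate sweeps over proliferation, apoptosis,
    division-axis, adhesion and contractility conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    EBImage
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
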