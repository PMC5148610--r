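Package: oplconnect
Title: Photoreceptor-to-Bipolar-Cell Connectivity Analysis in the Outer Retina
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the connectivity between photoreceptors
    (cone pedicles and rod spherules) and bipolar cells in serial
    block-face electron microscopy reconstructions of the mouse outer
    plexiform layer. Implements geometric contact-set features and
    RBF-SVM classification of synaptic versus non-synaptic contacts,
    rule-based identification of S-cones from CBC9 connectivity with an
    exact binomial plausibility test, subdivision of type 5 cone bipolar
    cells via starburst-amacrine-band-corrected axonal depth profiles,
    PCA, Gaussian mixtures and a mosaic-overlap cost refinement, and
    convergence, divergence, coverage-factor and bootstrap statistics.
    Includes a fully labelled synthetic outer-plexiform-layer generator
    so the whole pipeline is testable without volume data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    generics,
    stats,
    grDevices,
    utils,
    e1071,
    mclust,
    mgcv,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
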