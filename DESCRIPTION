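Package: hqsar
Title: Hologram QSAR Modelling and Validation for Congeneric Inhibitor Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fragment-hologram quantitative structure-activity relationship
    (HQSAR) modelling for congeneric small-molecule inhibitor series, built
    around a matrix metalloproteinase-12 (MMP-12) inhibitor case study.
    Molecules are fragmented into connected heavy-atom subgraphs, fragments
    are canonicalised under configurable distinction flags (atoms,
    connections, hydrogens, bonds, chirality, donor/acceptor) and hashed
    into fixed-length hologram count vectors, which are related to pIC50 by
    partial least squares with leave-one-out cross-validation. Includes
    hologram-length model search, Y-randomization, external validation
    (predictive r2, Golbraikh-Tropsha criteria, rm2 metrics), an Euclidean
    normalized-mean-distance applicability domain, per-atom contribution
    maps, and a synthetic congeneric-series generator with known
    fragment-additive activity for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
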