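Package: epiblup
Title: Mixed-Model GWAS for Additive and Epistatic Effects via GBLUP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Linear mixed-model association machinery for structured
    populations: single-marker and window-based additive scans under the
    P3D-approximated Q+K model and by back-solving marker effects from a
    fitted GBLUP model, together with exhaustive pairwise scans for
    additive-by-additive epistasis under the extended Q+K, Q+2K and
    REMMA (extended GBLUP back-solving) models. Includes restricted
    maximum likelihood estimation for one- and two-kernel models,
    genomic relationship matrix construction (additive and epistatic),
    LD-based marker pruning, a phenotype simulator with accept-reject
    calibration of realised variance components, and tools for
    comparing scan methods through threshold-filtered correlations of
    -log10(p) values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
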