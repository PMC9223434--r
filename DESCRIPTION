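Package: aucsens
Title: Drug-Target-Oriented Randomized Sensitivity Analysis for ODE Pathway Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-at-a-time sensitivity analysis of ordinary differential
    equation models of signaling pathways, oriented at molecular drug-target
    discovery. For each kinetic parameter a population of multiplicative
    drug-effect alteration factors is sampled (log-normal by default,
    emulating heterogeneous cell-to-cell drug response), the model is
    re-simulated one alteration at a time, and a signed sensitivity index is
    computed as the ratio of the area under the curve (AUC) of the output
    change to the AUC of the nominal output. Averaging the index over the
    sampled population yields a ranking that separates parameters whose
    inhibition amplifies the chosen output from those whose inhibition
    suppresses it. A classical local sensitivity-function ranking based on
    the AUC of finite-difference sensitivity functions is included as a
    comparison baseline, together with analytically solvable toy models,
    illustrative oscillatory and cascade demonstration models, parameter
    inventories for the p53/Mdm2 and IFN-beta JAK/STAT case studies, and a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
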