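Package: coopunfold
Title: Multistate Cooperative Analysis of Chemical Protein Unfolding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing chemical denaturation of proteins with a
    multistate cooperative (Zimm-Bragg) model. Computes unfolding isotherms
    and free-energy profiles from a denaturant binding constant, a
    cooperativity parameter and the number of residues in the cooperative
    unit, using the exact 2x2 transfer-matrix partition function or its
    largest-eigenvalue approximation. Fits the cooperative model and the
    rival linear extrapolation method (LEM) to experimental isotherms,
    extracts unfolding entropy and enthalpy from temperature series of free
    energies, and models calorimetric denaturant titrations. Includes a
    synthetic-data generator, built-in literature parameter tables, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
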