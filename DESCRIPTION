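Package: mtmpbpk
Title: Permeability-Limited Whole-Body PBPK Modeling for Mithramycin Analogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A middle-out physiologically based pharmacokinetic (PBPK) workflow
    for mithramycin (MTM) and its tryptophan-conjugated analog MTMSA-Trp. The
    package provides a permeability-limited whole-body PBPK simulator for IV
    bolus and infusion regimens, Poulin-Theil extracellular tissue-to-plasma
    partition coefficient prediction, non-compartmental analysis with the
    log-linear trapezoidal rule, calibration of the specific permeability-
    surface-area product against mouse plasma pharmacokinetics, three
    interspecies human clearance prediction methods (additional clearance,
    three-species allometry, monkey single-species scaling), predictive
    performance statistics (fold error, AFE, log-scale RMSE), one-at-a-time
    parameter sensitivity analysis, and a synthetic study generator for
    end-to-end testing. Species physiologies are bundled from open literature.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
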