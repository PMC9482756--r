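Package: tloop
Title: T-Loop Archwire Mechanics and Tooth-Movement Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closed-form mechanics of the orthodontic T-loop archwire bend:
    vertical-arm and arc-portion deflection profiles and restoring forces,
    superposed into the total orthodontic force, coupled to a viscous-medium
    (waxy typodont) resistance model and constant-acceleration kinematics to
    predict tooth displacement. Ships a catalogue of clinical stainless-steel
    and Australian archwires, a reference dataset of calculated, simulated
    and experimentally measured displacements over a grid of loop clearance
    distances, model-versus-experiment deviation and trend analyses, an
    independent finite-difference boundary-value beam solver that validates
    every closed form, and least-squares calibration of the model's
    composite parameters with a synthetic-data generator for
    parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
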