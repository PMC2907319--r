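Package: stemstab
Title: Primary Stability Analysis of Cementless Hip Stems from
    Six-Sensor Motion Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and analyses in-vitro primary-stability tests of
    cementless femoral hip stems. Provides a forward model of a
    six-LVDT (linear variable differential transformer) measurement
    array, recovery of the six degree-of-freedom implant-bone pose from
    the sensor readings with analytic error propagation, static
    equilibrium of the loading rig with and without an abductor-muscle
    cable, extraction of migration and micromotion components and their
    translational and helical-axis resultants from cyclic loading, a
    calibrated synthetic-specimen generator, and a split-plot
    repeated-measures ANOVA with Student-Newman-Keuls post hoc
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
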