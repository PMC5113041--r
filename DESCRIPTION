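Package: elegansim
Title: Observation-Driven Agent-Based Simulation of C. elegans Embryogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An agent-based simulator of early Caenorhabditis elegans
    embryogenesis (4-cell to ~350-cell stage) in which each cell is an agent
    whose division timing, division direction and migration path are driven by
    statistical summaries of observed wild-type behaviour. Cells migrate toward
    per-cell target positions inside an ellipsoidal eggshell, divide at
    stochastically perturbed scheduled times, and separate along recorded
    division axes. The package reads the three observation tables that drive
    the model (division schedule, division directions, target positions),
    writes and reads the 20-field nuclei-style snapshot format, rebuilds cell
    lineage trees from snapshot streams, and provides the quantitative
    validation suite used to compare simulated embryos against wild-type
    reference data (cell-count RMSE, founder-cell cycle analysis with
    error propagation, dividing-position deviations) together with a synthetic
    fixture generator for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
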