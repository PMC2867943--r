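Package: sepalsim
Title: Stochastic Simulation of Cell Size Patterning by Endoreduplication
    Timing in the Arabidopsis Sepal Epidermis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An agent-based simulator of the outer (abaxial) sepal epidermis
    of Arabidopsis thaliana in which each cell, over three "patterning" cell
    cycles, stochastically either divides or irreversibly enters the
    endocycle.  The timing of entry into endoreduplication sets terminal
    ploidy (2C-16C) and, through continued growth without division, terminal
    cell size, reproducing the characteristic mixture of giant and small
    pavement cells.  The package couples the simulator to an analytic
    branching ("population") model that maps per-cycle endoreduplication
    probabilities to expected terminal ploidy fractions, an inverse fitter
    that recovers those probabilities from flow-cytometry ploidy fractions
    (with multinomial bootstrap intervals), and measurement utilities for
    tracked-lineage tables: cell-cycle-time histograms, daughter-size
    asymmetry, and cell-size distribution comparisons.  A small command-line
    front-end drives simulation, fitting and summary statistics from
    JSON/CSV files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
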