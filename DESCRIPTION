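Package: bcrsyk
Title: Mechanistic Modelling of B-Cell-Receptor Signalling Through Syk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A mass-action ordinary-differential-equation model of early and
    downstream B-cell-receptor (BCR) signalling, covering receptor engagement,
    Syk and Lyn kinase activation, the SHP1/Csk/Cbp regulatory loop, the
    BLNK/BTK/PLC2g medial pathway, and reconstructed MAPK/Erk and IkB/NF-kB
    branches, in both wild-type and analog-sensitive Syk-AQL (orthogonal
    inhibitor) scenarios.  On top of the simulator the package provides
    first-order Sobol sensitivity screening with a time-median rule, Latin
    hypercube parameter screening against normalized Western-blot-style
    observations with a linear noise model, ligand binding-rate response
    surfaces with power-law affinity collapse, Syk allocation analysis, and a
    seeded synthetic-data generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
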