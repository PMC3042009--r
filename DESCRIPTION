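Package: stat1dyn
Title: Distributed-Delay Modeling and Multi-Dose Fitting of IFN-gamma/STAT1
    Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic distributed-delay (linear chain) ODE model of the
    IFN-gamma receptor / STAT1 / SOCS1 signaling pathway in pancreatic cancer
    cells, together with the measurement arithmetic of the assays used to probe
    it (immunoblot loading-control normalization, qPCR relative expression,
    confocal nuclear:cytoplasmic ratios, tumor volume estimation), an
    observation model with immunoblot scaling factors, chi-squared
    multi-experiment parameter estimation by hybrid simulated annealing plus
    local refinement, and a scaling-factor sweep that converts a cost-function
    plateau into an upper bound on the nuclear phospho-STAT1 fraction. A
    synthetic-data generator reproduces the statistical structure of the
    experimental time series so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
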