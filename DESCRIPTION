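Package: polysynergy
Title: Network Pharmacology Prediction and Mechanistic Simulation of Drug
    Combination Synergy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end polypharmacology toolkit for kinase-inhibitor
    combination discovery in cancer cell lines. Implements the TIMMA
    set-theoretic model that predicts multi-target inhibition sensitivity
    from single-drug sensitivity scores and kinome-wide binding-affinity
    (Kd) profiles, together with experimental synergy scoring
    (Bliss excess volume over dose-response matrices, highest-single-agent
    scores, multiplicative siRNA double-knockdown synergy, qPCR and
    CRISPR assay transforms), Kd- and expression-based deconvolution of
    the target pairs behind a drug combination, and a stochastic
    signaling-network simulator of growing, dividing cell populations
    with an ordinary-differential-equation twin for steady-state
    verification and parameter sensitivity analysis. A synthetic-data
    module generates every input with planted ground truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    deSolve,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
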