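Package: burstsim
Title: Multi-Fidelity Simulation of Transcriptional Bursting in Gene
    Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulators and analysis tools for gene regulatory motifs with
    telegraph-promoter transcriptional bursting. Implements four model tiers
    for a delayed auto-negative feedback loop: the exact delayed stochastic
    simulation algorithm with protein-dependent promoter switching, a
    piecewise-deterministic process (bursting noise only), an extended
    chemical Langevin equation whose mRNA noise carries an explicit
    bursting variance term, and a linear-noise approximation with
    closed-form power spectra. Also covers the bistable genetic toggle
    switch with bursting promoters. Includes ensemble periodograms,
    stationary-moment estimators, relative-error sweeps over burst
    frequency and system size, and waiting-time extraction for
    noise-induced state switching.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    optparse
Config/testthat/edition: 3
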