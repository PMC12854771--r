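Package: ionspike
Title: Multiscale Coupling of Ion-Channel Simulations to Neuronal Spiking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links molecular-level ion-channel behaviour to neuronal
    membrane-potential dynamics. Provides a coarse-grained Metropolis Monte
    Carlo simulator of voltage-gated Na+/K+ channels embedded in a binary
    lipid membrane on a square lattice; a compartmental Hodgkin-Huxley cable
    solver with SWC morphology support; conversion of single-channel
    conductances from ion-permeation counting into variant-specific synaptic
    scaling factors driving Poisson-stimulated synaptic experiments; and a
    bidirectional coupling loop in which Monte Carlo patch currents drive the
    membrane-potential solver while the evolving potential feeds back into the
    channel gating energetics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
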