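Package: spinesync
Title: Event-Driven Co-Simulation of Electrical and Biochemical Signaling in Dendritic Spines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained multiscale simulator for synaptic plasticity in
    medium spiny neuron dendritic spines.  An event-driven meta-simulator
    synchronizes a fast compartmental electrical model (Hodgkin-Huxley and
    Boltzmann-gated channels, thin-shell calcium, double-exponential synapses)
    with a slow deterministic kinetic model of the spine signaling network
    (allosteric calmodulin, CaMKII, calcineurin, DARPP-32/PP1, AMPA-receptor
    phosphorylation).  Calcium flux and phosphorylated-receptor counts are
    exchanged between the two models around stimulation events only, with
    fixed-step and on-demand synchronization strategies available for
    comparison.  Utilities cover stimulation-train construction, spine-density
    profile fitting and spine placement on reduced dendritic morphologies,
    experiment orchestration and plasticity summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
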