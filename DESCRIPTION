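Package: dikaryosim
Title: Spatial Simulation of Basidiomycete Life Cycles and Nuclear Selection
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A spatially explicit stochastic simulator of the Basidiomycete
    life cycle on a toroidal lattice. Each haploid nucleus carries a heritable
    three-way fitness trade-off between vegetative growth, spore production
    and mating success; mycelia grow, die, mate and sporulate under one of
    three life-cycle scenarios (diploid, standard dikaryon with di-mon
    matings, or a hypothetical open dikaryon that also permits di-di nuclear
    exchange). The package provides the lattice and mating primitives, a fast
    compiled updating engine, per-generation population metrics (dikaryon
    fraction, per-role fitness means, parasitic-nucleus fractions), and
    scripted experiment protocols: dominance and linkage sweeps, growth by
    death-rate environmental scans, habitat fragmentation, and invasion
    competitions for an allele conferring dikaryotic male function.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
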