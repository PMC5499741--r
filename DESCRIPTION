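Package: scanoise
Title: Translational Gene-Expression Noise from 5'UTR Structure
Version: 0.1.0
Authors@R:
    person("Scanoise", "Developers", email = "maintainer@scanoise.org",
           role = c("aut", "cre"))
Description: Tools for studying how structural elements in an mRNA 5'UTR
    generate translational gene-expression noise in budding yeast. Provides
    an exact Gillespie stochastic simulator of a two-state-promoter gene
    expression model extended with reversible mRNA folding, closed-form
    moment oracles (telegraph and two-stage birth-death), synthetic
    generators for smFISH-like mRNA count populations and single/dual
    channel flow-cytometry event tables, a density-centre radial-gating
    pipeline for coefficient-of-variation statistics, dual-reporter
    intrinsic/extrinsic noise decomposition, and Poisson/negative-binomial
    maximum-likelihood fitting of per-cell mRNA counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
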