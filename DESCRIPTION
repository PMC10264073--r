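Package: adaptrack
Title: Adaptive Single-Molecule Tracking and Motion Analysis for
    Biomolecular Condensates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of single-molecule localization microscopy data from
    phase-separated (condensate) systems. Determines condensed-phase
    boundaries and enrichment folds from localization densities, links
    localizations into trajectories with an error-optimal adaptive search
    range, fits a two-state (confined/mobile) hidden Markov diffusion model
    and a model-free correlation-based step classification, relates the
    kinetic diffusion parameters to the equilibrium enrichment fold, and
    provides Monte Carlo simulators (ground-truth localization scenes,
    equilibrium two-phase diffusion, and in-silico FRAP) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    igraph,
    EBImage,
    minpack.lm,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
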