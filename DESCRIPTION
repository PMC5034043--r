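Package: fepsel
Title: Alchemical Free Energies, Hydrogen-Bond Occupancy and Affinity-Based
    Profiling for Receptor Interface Selectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for studying asymmetric small-molecule binding
    to the subunit interfaces of heteropentameric ligand-gated ion channels.
    Provides a Metropolis Monte Carlo host-guest simulator with a
    lambda-scalable composite Gaussian-well binding site, Zwanzig
    exponential-averaging free-energy estimation over decoupling windows with
    the 1 M standard-state volume correction and dissociation-constant
    uncertainty bands, geometric hydrogen-bond occupancy analysis of
    trajectories, the pKD versus hydrogen-bond-probability selectivity
    regression, quantitative isobaric-tag (TMT) affinity-based protein
    profiling enrichment and protection classification, and Hill dose-response,
    Cheng-Prusoff and exponential photolysis-decay fits. Synthetic-data
    generators with recorded ground truth replace the atomistic molecular
    dynamics engine and the mass spectrometer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
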