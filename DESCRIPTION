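Package: smkinetics
Title: Single-Molecule Kinetic Fingerprinting Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of single-molecule fluorescence kinetic
    fingerprinting experiments, in which a dye-labeled probe binds a surface-
    captured target transiently and repeatedly. Provides a kinetic Monte Carlo
    trace and movie simulator with ground-truth labels, fluctuation-map spot
    detection and trace extraction from image stacks, two-state hidden Markov
    model idealization with dwell-time extraction, kinetic fingerprint
    filtering and mixture classification of kinetic subpopulations,
    exponential dwell-time distribution fitting with rate-constant and
    affinity estimation, Rank-Surprise burst detection on binding-event
    trains, and windowed Fano-factor statistics with chi-square confidence
    bands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    mclust,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
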