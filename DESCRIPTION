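Package: minitrap
Title: Analysis of Mini-Ensemble Myosin Laser-Trap Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing displacement records from mini-ensemble
    myosin optical (laser) trap assays. Provides a synthetic-trace simulator
    (Ornstein-Uhlenbeck bead fluctuations with Gillespie motor attachment
    kinetics and Bell-type load-dependent detachment), equipartition trap
    stiffness calibration, binding-event detection by a two-state hidden
    Markov model on running mean/variance features with changepoint boundary
    refinement, per-event metrics (lifetime, peak displacement and force,
    time at peak force), Bell-bond fitting of load-dependent detachment
    rates, head-count bookkeeping from displacements, and nearest-neighbour
    reach geometry for motor surface densities measured by localization
    microscopy.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
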