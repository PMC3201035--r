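Package: viaspace
Title: Efficient Exploration and Volume Estimation of Viable Parameter Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes the viable space of a parameterized model, i.e. the
    region of a box-bounded parameter space where a cost function stays below a
    viability threshold. Combines a global out-of-equilibrium adaptive
    Metropolis Monte Carlo exploration (OEAMC) with a local multiple
    ellipsoid-based sampling (MEBS) built on minimum-volume enclosing
    ellipsoids, then estimates the viable volume by stratified Monte Carlo
    integration over a union of covering ellipsoids with an overlap-once
    integrand. Ships spherical-shell benchmark problems with analytic viable
    volumes and a twelve-parameter two-feedback-loop biochemical oscillator
    case study, including feedback-loop essentiality classification,
    random-walk robustness, and viable-space connectivity analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
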