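Package: famstates
Title: Parental Marital States and Child Outcomes from Longitudinal Family Histories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying how time-varying parental marital states relate
    to child survival, growth, and education in longitudinal demographic data.
    Builds censored child-year panels from family event histories using a
    branching-tree classifier of parental marriage states (deceased, unmarried,
    step-parent, polygynous, external), defines Bayesian hierarchical models for
    discrete-time survival, log-normal height and weight-for-height, and
    zero-inflated Poisson education with Gaussian-process-smoothed age-specific
    effects, fits them by Hamiltonian Monte Carlo, and summarises posterior
    contrasts between family structures with highest-posterior-density
    intervals. Includes a synthetic family-history generator with Markov
    marital-state dynamics for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
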