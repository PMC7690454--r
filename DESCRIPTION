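Package: boolpop
Title: Continuous-Time Stochastic Boolean Networks with Cell-Population Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trajectory-based continuous-time Markov simulation of
    rate-annotated Boolean networks, extended to interacting cell
    populations: periodic update steps remove dying cells, double dividing
    cells, track the total population size, and recompute receptor
    transition rates from population-averaged ligand probabilities.
    Ships two logical models of immunogenic cell death (a phenomenological
    and an extended tumour-immune model), intervention scenarios (CD28
    knock-out, IL-2 treatment, suppressed clonal expansion), a
    single-parameter sensitivity-scan pipeline, an exact master-equation
    oracle for validation, and a generator of synthetic benchmark networks
    with closed-form transient solutions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
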