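Package: cscdyn
Title: Coordinated Hierarchical and Stochastic Dynamics of Cancer Stem Cell
    Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic and stochastic models of interconverting cancer
    stem cell (CSC) and non-stem cancer cell (NSCC) subpopulations. Provides a
    generation-structured linear ODE model of CSC self-renewal, asymmetric
    division, differentiation, NSCC proliferation with replicative senescence,
    and stochastic NSCC-to-CSC transition; equilibrium and parameter
    sensitivity analysis of the long-run CSC proportion; a radiation-response
    extension in which cell kill follows DNA double-strand-break repair and
    lethal mis-repair kinetics; a bounded-lattice cellular automaton
    counterpart of the ODE model; simulated-annealing parameter fitting used
    to test whether imperfect flow sorting alone can explain phenotypic
    equilibrium; and generators of synthetic experimental data (division-event
    counts, one-day sorted-population counts, noisy CSC-proportion time
    courses) with known ground truth for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
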