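Package: homeostat
Title: Homeostatic-Ensemble Mechanics and Free-Energy Forecasting of Stem
    Cell Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Samples the homeostatic (maximum morphological entropy)
    ensemble of single-cell morphological microstates on elastic or
    island-patterned substrates by Markov chain Monte Carlo, computes the
    normalized Gibbs free energy of each microstate (2D Ogden passive
    elasticity, stress-fibre cytoskeleton in chemical equilibrium with a
    uniform unbound protein pool, Winkler substrate tractions), and
    forecasts human mesenchymal stem cell lineage commitment
    (osteoblast, myoblast, adipocyte, undifferentiated) from the
    cytoskeletal free-energy distribution via a central-limit-theorem
    band classifier with media-specific lineage bands. Includes
    morphometric observables (normalized area, aspect ratio, total
    traction, stress-fibre polymerization), kernel density summaries,
    immunofluorescence-like renders, and end-to-end stiffness, adhesive
    island and ROCK-inhibition in-silico experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    MASS,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
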