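Package: surfplast
Title: Surface Plasticity Analysis of Protein Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the conformational "surface plasticity" of protein
    ensembles such as antibody paratopes and antigen epitopes. Per-frame
    Gaussian atom-density grids are averaged over an ensemble; the temporal
    standard deviation of the density, optionally Gaussian-smoothed, maps
    where the molecular surface fluctuates. Companion analyses include
    Kabsch superposition and RMSF profiles, Cartesian C-alpha principal
    component analysis, Boltzmann reweighting of Gaussian-accelerated
    molecular dynamics (gaMD) samples via a Maclaurin-series approximation
    of the exponential weight, free-energy surfaces over principal
    components, and conformational-selection statistics (binding-competent
    state occupancy and population shift). Synthetic-ensemble generators
    with known ground truth support end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    generics,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
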