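Package: mdcm
Title: Minimal Distance Constraint Model for Protein Flexibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical-mechanical network-rigidity analysis of proteins with the
    minimal Distance Constraint Model (mDCM). Builds body-bar constraint networks
    from all-atom structures (quenched covalent bonds, fluctuating hydrogen bonds
    with geometry-dependent enthalpies, native/disordered torsion forces), runs the
    (6,6) body-bar pebble game to decompose each framework into flexible, isostatic
    and over-constrained clusters, and averages mechanical properties over a
    two-dimensional free-energy landscape in the number of native torsions and
    hydrogen bonds. Outputs quantified stability/flexibility relationships: heat
    capacity curves and melting temperatures, per-residue flexibility index
    profiles, pairwise cooperativity-correlation maps, and mutant-versus-wild-type
    response statistics (normalized deltas, five-bin histograms, chi-square tests
    against the Gaussian null, stratified response ratios, and median-normalized
    B-factor comparisons). Includes seeded synthetic-data generators for toy
    frameworks with known rigidity, polymer pseudo-proteins with designed hydrogen
    bond networks, synthetic heat-capacity curves, and Gaussian null profiles, plus
    simulated-annealing parameter fitting to experimental heat-capacity data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
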