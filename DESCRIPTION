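Package: resmosaic
Title: Landscape Analysis of Herbicide Resistance and Neutral Genetic Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether herbicide resistance across a weed's
    range evolved in independent local hotspots or spread by gene flow.
    Combines Weibull dose-response estimation (ED50 with bootstrap species
    confidence intervals and population classification), microsatellite
    population-genetic structure statistics (Weir-Cockerham theta, R_ST,
    hierarchical AMOVA, Nei and Cavalli-Sforza-Edwards distances, exact
    Hardy-Weinberg and genotypic linkage-disequilibrium tests, null-allele
    EM estimation), spatial analyses (Moran's I correlograms, Mantel
    isolation-by-distance regressions, principal coordinates), and
    approximate Bayesian computation model choice among pre- versus
    post-herbicide admixture scenarios using a built-in coalescent
    simulator of microsatellites under stepwise mutation. Includes
    synthetic-data generators emulating a replicated greenhouse
    dose-response design and island/stepping-stone population structure,
    so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    geosphere,
    nnet,
    MASS,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
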