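Package: famfluct
Title: Cross-Species Gene-Family Abundance Fluctuations and Horizontal Transfer Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how horizontal gene transfer, gene duplication and gene
    loss shape the species-to-species variability of gene-family copy number in
    prokaryotes. Implements a collisional stochastic model of genome exchange
    (pairwise Bernoulli gains, multinomial loss/duplication) with its mean-field
    predictions (stationary Poisson profile, overdispersion formula, negative-binomial
    grazing limit, exponential relaxation), the cross-species abundance-fluctuation
    statistics computed in sliding genome-size bins (sampling weight, L1 distance to
    Poisson, log inverse Fano factor, occurrence, transfer fraction), classification
    of families into overdispersed, Poisson-like and peaked profiles, Fisher exact
    functional-category enrichment, plasmid log-ratio scores, class-restricted genome
    distances, a synthetic family-by-genome ensemble generator with planted classes,
    and a reproducible end-to-end pipeline over TSV inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
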