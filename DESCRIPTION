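Package: envcomplexity
Title: Microbial Community Yield and Diversity Scaling with Environmental Complexity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying how microbial community growth yield and
    taxonomic diversity scale with the number of carbon sources in a medium at
    fixed total carbon. Provides combinatorial environment designs (hierarchical
    pairings and all-subsets schemes with equal total carbon), a consumer
    resource model with Monod uptake kinetics, metabolic byproduct secretion and
    serial batch passaging, statistical ensembles over random resource-preference
    matrices with a niche-overlap summary, environmental-epistasis metrics for
    growth yield, species richness and Shannon entropy, outcome-type
    classification of combined-environment communities, a preprocessing pipeline
    for plate-reader yield tables and taxon relative-abundance tables (blank
    correction, MAD outlier removal, growth calls, replicate averaging, UPGMA
    clustering), and synthetic-data generators that emulate the experimental
    designs end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    ape,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
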