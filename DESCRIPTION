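Package: phylohab
Title: Phylogeny Versus Habitat in Microbial Ecology and Comparative Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies habitat ubiquity, preference and relative abundance of
    microbial taxa from large collections of metagenomic taxonomic profiles,
    classifies lineages as soil-preferring or non-soil-preferring and as
    habitat generalists or specialists, and partitions variation in genomic
    features and binary metabolic traits between phylogeny and habitat using
    type III ANOVA percentage contributions and McFadden pseudo-R-squared
    drops from logistic regression. Includes a nearest-centroid life-history
    classifier built on two genomic investment indices (regulatory
    flexibility and resource acquisition), and a synthetic-data generator
    that plants recoverable habitat-preference, variance-share and cluster
    structure so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    MASS,
    optparse
Config/testthat/edition: 3
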