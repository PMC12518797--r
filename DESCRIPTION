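Package: apisym
Title: Host Specificity and Co-Diversification Analysis for Honeybee Gut Symbionts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for comparative gut-metagenomics of host-associated
    bacterial communities, built around the five Apis honeybee species. Implements
    species detection from coverage profiles, SNV and popANI strain-level
    dissimilarities, Rohde's host-specificity index and three-way specificity
    classification, beta-diversity turnover partitioning, PERMANOVA with the
    omega-squared effect size, subsampled Mantel phylosymbiosis testing with FDR
    control, a node-by-node Hommola co-phylogeny scan with a second-order
    permutation null, gene-level RPKM functional profiling with robust Aitchison
    distances, and a seeded synthetic-data generator (host tree, symbiont trees
    under a co-speciation/host-switch/loss model, communities, allele profiles,
    gene tables) so every stage is testable without raw sequence data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    phangorn,
    jsonlite
Config/testthat/edition: 3
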