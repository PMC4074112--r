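Package: motupipe
Title: Fungal ITS1 Amplicon MOTU Pipeline and Elevation-Gradient Community Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable re-implementation of a fungal ITS1 amplicon
    community analysis pipeline: deterministic greedy centroid clustering of
    reads into molecular operational taxonomic units (MOTUs) at 97 percent
    identity, consensus taxonomic assignment from tabular BLAST hits with
    phylum-specific ITS1-variability thresholds, taxonomy- and GI-based MOTU
    merging and quality filtering, singleton-adjusted rarefaction richness with
    a group-redistribution estimator, and presence/absence composition analysis
    (correspondence analysis and nested PERMANOVA with strata-restricted
    permutations). A synthetic-data module simulates hierarchical sampling
    designs, niche-structured communities, reads and noisy BLAST-hit tables
    with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    Biostrings,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
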