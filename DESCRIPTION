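Package: ecoassembly
Title: Null-Model Inference of Microbial Community Assembly Processes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the ecological processes structuring microbial
    communities from an ASV count table, a rooted phylogeny and sample
    metadata. Implements beta mean nearest taxon distance (betaMNTD), its
    standardized effect size betaNTI under phylogeny-shuffling null models,
    the abundance-based Raup-Crick metric on Bray-Curtis dissimilarity
    (RC-bray), and the five-way classification of pairwise community
    turnover into heterogeneous selection, homogeneous selection, dispersal
    limitation with drift, homogenizing dispersal, and drift. Also provides
    Hill-number alpha diversity with repeated rarefaction, Bray-Curtis and
    weighted UniFrac distances, PCoA, PERMANOVA, dispersion homogeneity
    tests, core-taxon detection, phylum-chemistry correlations, and Mantel
    tests against geographic and soil-chemistry distances, plus a synthetic
    study generator with known assembly regimes for validating process
    recovery.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    geosphere,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vegan,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    phyloseq,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
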