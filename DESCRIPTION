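Package: mlno
Title: Multi-Layer Network with Omnibus Test for Multiple Unbalanced Binary Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint association testing between a single genetic variant and many
    correlated binary phenotypes with extremely unbalanced case-control ratios,
    as found in biobank disease codes. Builds a multi-layer network from case
    co-occurrence among individuals with at least one case status, clusters
    phenotypes by complete-linkage hierarchical clustering scored by network
    modularity, merges clustered phenotypes by logical union, and combines
    per-cluster score statistics with an omnibus chi-square test (MLN-O).
    Includes the comparator tests MANOVA (Wilks' lambda), USAT, TATES and
    MultiPhen, a block-factor liability-threshold simulator for unbalanced
    binary traits, and a Monte-Carlo harness for type I error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
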