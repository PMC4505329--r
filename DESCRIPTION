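Package: otuflux
Title: OTU Clustering, Cross-Edition Set Algebra and Taxonomic Diversity
    Flux for Amplicon Surveys of Microbial Mat Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for tracking a microbial community across repeated
    spatiotemporal samplings ("editions") with 16S rRNA V3 amplicon data:
    read-level quality and preprocessing filters, Needleman-Wunsch pairwise
    distances, single-linkage preclustering (denoising), hierarchical OTU
    clustering at 97 percent identity with singleton removal and consensus
    sequences, rarefaction and ACE richness, cross-edition OTU superset
    construction with singleton/doubleton/tripleton multiplicity censuses,
    the Relative Taxonomic Diversity Index T_r with its per-phylum
    breakdown, classical alpha-diversity indices (Simpson dominance,
    Shannon diversity and equitability), relative-abundance leaderboards,
    and community-environment association statistics (Pearson, Bray-Curtis,
    Euclidean).  A seeded synthetic-data generator produces multi-edition
    amplicon systems with known ground truth so every pipeline stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
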