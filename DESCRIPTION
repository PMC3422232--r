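Package: pbdpart
Title: Partitioning Phylogenetic Beta Diversity into Lineage Turnover and
    Phylogenetic Diversity Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Additive decomposition of pairwise phylogenetic beta diversity.
    The PhyloSor and UniFrac branch-length dissimilarity indices are split
    into a 'true' lineage-turnover component and a component driven by
    phylogenetic diversity differences between communities, mirroring the
    turnover/nestedness partition of the Sorensen and Jaccard indices for
    species composition. Includes Faith's phylogenetic diversity on rooted
    trees, pairwise drivers over site-by-species incidence tables, a
    richness- and composition-preserving tip-shuffling null model with
    standardized effect sizes, Yule and PDA random tree simulators, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
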