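Package: lanticor
Title: Correlational Networking of Lanthipeptide Precursors and Unclustered Proteases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links groups of lanthipeptide precursor peptides to candidate
    leader-peptide proteases encoded outside their biosynthetic gene clusters.
    Implements annotation-keyword and Pfam-domain mining of candidate
    proteases, identity-threshold connected-component grouping of sequences,
    per-genus Spearman correlation networks over genome occurrence counts
    with one-sided t-test p-values and Benjamini-Hochberg adjustment,
    prioritization filters on correlation strength, adjusted p-value and
    genome support, and a transcriptomic refinement that intersects genomic
    correlation evidence with TPM-based co-expression across strains. Ships a
    seeded synthetic-data generator emulating the statistical structure of
    genus-stratified gene-family occurrence data so the whole workflow is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
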