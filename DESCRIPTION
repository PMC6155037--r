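Package: mirpair
Title: Integrative miRNA-mRNA Analysis of the Hair-Follicle Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for the joint analysis of small-RNA and
    mRNA sequencing data across the telogen-anagen transition of the
    hair-follicle cycle. Provides small-RNA read filtering with per-category
    accounting, exact-test differential expression on count matrices,
    seed-match microRNA target prediction with nearest-neighbor duplex free
    energies and a context-score percentile filter, fold-change quadrant
    classification of miRNA-mRNA pairs, hypergeometric GO/KEGG enrichment,
    negative-regulation network construction with SIF/GraphML export, and
    2^-ddCt qPCR relative quantitation. A synthetic-data generator with a
    recorded truth set makes every stage verifiable without access to raw
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
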