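Package: markscape
Title: Promoter-Centric Fold-Enrichment Analysis of Histone Marks Across Cell Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparing histone-modification ChIP
    enrichment (e.g. H3K4me3 and H3K4ac) at gene promoters across cell
    lines. Computes RPKM-based fold enrichment over a percentile-floored
    input, classifies marked promoters, partitions them across three
    conditions, scores pairwise differential marking, tests gene-set
    over-representation with an exact binomial tail, clusters TSS-centred
    fold-enrichment profiles with seeded k-means, and integrates RNA-seq
    expression by mark category. Includes a negative-binomial synthetic
    data generator with planted signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
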