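Package: glrevo
Title: Gene-Family Expansion, Selection and Expression Analysis for Plant
    Glutamate-Like Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evolutionary analysis of a plant gene family
    (glutamate-like receptors, GLRs): candidate screening and pseudogene
    filtering, PSSM-based domain-architecture calls, homolog-pair detection,
    collinearity chaining and duplication-mode classification (tandem,
    WGD/segmental, dispersed), tandem-array statistics, linear expansion and
    orthology series, physico-chemical conservation profiling with sliding
    windows, intron projection onto protein alignments, dN/dS estimation by
    Nei-Gojobori counting and GY94/M0 maximum likelihood, neighbor-joining
    trees with bootstrap and marker-anchored subfamily classification, and
    qPCR/RNAseq expression normalisation with K-means clustering. Includes
    synthetic-genome generators with planted ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    igraph,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
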