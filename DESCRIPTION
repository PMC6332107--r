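Package: HaploPop
Title: Population Structure and Demographic History from mtDNA Haplotype
    Alignments
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for mitochondrial control-region population genetics on
    aligned haplotype sequences: haplotype collapsing and site
    classification, Nei diversity indices, Kimura two-parameter distances
    with neighbor-joining trees and bootstrap support, median-joining
    haplotype networks, analysis of molecular variance (AMOVA) with
    permutation tests, Weir-Cockerham pairwise FST and corrected average
    pairwise differences, Dirichlet-multinomial model-based clustering of
    individuals into panmictic groups, Mantel tests of isolation by
    distance, Tajima's D and Fu's Fs neutrality tests with coalescent
    p-values, mismatch-distribution fitting under the sudden-expansion
    model, entropy-based substitution-saturation assessment, and a
    structured-coalescent sequence simulator that generates alignments
    with known truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    igraph,
    jsonlite,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
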