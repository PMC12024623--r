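Package: gsbb
Title: Genomic Complexity Metrics and Phylogenetic Contrasts for Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes two k-mer based genome complexity metrics, the Genomic
    Signature (GS, maximal excess of absolute k-mer count deviation over a
    composition-matched shuffled baseline) and Biobit (BB, a nonlinear
    combination of the entropic and anti-entropic components of the k-mer
    entropy), together with six annotation-derived genome parameters and the
    hapax percentage. Provides phylogenetically informed downstream analysis:
    Pagel's lambda estimation, GLS trait correlations with Holm correction,
    simulation-based phylogenetic ANOVA, phylogenetic PCA on the evolutionary
    correlation matrix, and Blomberg's K, plus a synthetic-data generator
    emulating endosymbiont genome erosion (AT bias, deletions, insertion-
    sequence-like repeats) for end-to-end testing of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phytools,
    picante,
    rtracklayer
Config/testthat/edition: 3
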