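Package: aptevo
Title: Comparative-Genomic Signatures of Nocturnal Adaptation in Flightless Birds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A toolkit for the comparative-genomic analyses used to study
    nocturnal adaptation in ratites such as the kiwi. Implements a
    Goldman-Yang style 61-state codon substitution model with foreground /
    background branch omega estimation and likelihood ratio tests for
    lineage-specific shifts in selective pressure; dating of
    loss-of-function events from relaxed constraint on a focal branch;
    GC-bias-corrected copy-number estimation for collapsed multi-copy gene
    families such as olfactory receptors, with intact/pseudogene
    classification; Shannon-entropy profiling of receptor repertoire
    diversity with an exact Wilcoxon signed-rank comparison; k-mer-spectrum
    genome-size estimation and assembly summary statistics; hypergeometric
    category-enrichment screening with family-wise error control and
    species-specificity assignment; and a divergence screen of
    ultra-conserved non-coding elements. Synthetic-data generators emulate
    every input so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
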