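Package: retrofam
Title: Characterization of LTR Retrotransposon Families from Reference
    Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational characterization of long terminal
    repeat (LTR) retrotransposon families starting from curated reference
    elements: genome mining of full-length copies with structural
    validation (length/identity thresholds, TG..CA termini, target site
    duplications), family classification under the 80-80-80 rule with
    standardized RLC/RLG naming, insertion-time dating from 5'/3' LTR
    divergence under the Kimura two-parameter model, per-family LTR
    nucleotide diversity, qPCR standard-curve efficiency and relative
    copy-number / expression quantification by the delta-delta-Ct method
    (including geNorm normalizer stability and ANOVA with Fisher's LSD),
    and IRAP/REMAP dominant-marker diversity analysis (Jaccard similarity,
    UPGMA dendrograms, polymorphism summaries). A synthetic-data module
    generates genomes with planted insertions of known age, simulated Ct
    tables and species-structured marker matrices so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    ape,
    igraph,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vegan
Config/testthat/edition: 3
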