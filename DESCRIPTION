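Package: trnarr
Title: Discovery of Split and Permuted tRNA Genes in Archaeal Genomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Structural detection of tRNA genes and tRNA gene fragments in
    archaeal genomes with a constraint-based cloverleaf model, assembly and
    validation of trans-spliced (split) and circularly permuted tRNA gene
    candidates via bulge-helix-bulge (BHB) splice-junction enumeration and
    trans-pairing stem search, and an archaeal promoter identification
    pipeline (EM motif discovery, PSSM scanning, empirical P-values from
    Markov-chain virtual genomes, promoter-spacing outlier analysis). Includes
    a synthetic-genome generator that plants standard, intron-containing,
    split and permuted tRNA genes with machine-readable ground truth, so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
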