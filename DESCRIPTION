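Package: atacPatterns
Title: Latent Pattern Analysis and Transfer Learning for Single-Cell ATAC-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis framework for single-cell ATAC-seq count matrices built
    around a sparse Bayesian non-negative matrix factorization fit by Gibbs
    sampling. Decomposes peak-by-cell (or motif-by-cell) accessibility counts
    into an amplitude matrix over features and a pattern matrix over cells,
    assigns cells and features to patterns with the PatternMarker statistic,
    annotates pattern-marker peaks with genes, pathway overlap enrichment,
    transcription factor motif enrichment and fold accessibility, transfers
    learned patterns into other data sets by least-squares projection, and
    validates predicted transcription factor activity against matched
    single-cell RNA-seq via preranked gene set enrichment of TF regulons.
    Includes a synthetic data generator with planted cell populations for
    end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    pracma,
    fgsea
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
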