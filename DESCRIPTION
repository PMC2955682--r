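Package: codonscan
Title: Codon-Pair Log-Odds Scanning to Filter False-Positive Exon Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds empirical codon-pair log-odds substitution matrices from
    in-frame orthologous coding alignments, scans pairwise genomic DNA
    alignments for locally maximal high-scoring segment pairs in all six
    framings (three reading frames on both strands), assigns Karlin-Altschul
    P-values calibrated by simulation of a non-coding null model, and uses
    them to reject false-positive exon predictions produced by external gene
    finders. Includes a synthetic-data module that simulates
    synonymous-biased coding alignments, non-coding null alignments, and
    genomic mosaics with truth annotations, so the whole pipeline can be
    exercised and evaluated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    withr,
    stats,
    tools,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
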