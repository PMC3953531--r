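Package: kmermix
Title: Taxonomic Profiling of Shotgun Metagenomes by Sparse Nonnegative
    k-mer Mixture Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the taxonomic composition of a whole-genome shotgun
    (WGS) metagenomic read set all at once, instead of read-by-read. The
    pooled k-mer frequency vector of the sample is expressed as a sparse
    nonnegative mixture of the k-mer profiles of database genomes, and the
    mixture weights are recovered by a regularized nonnegative least-squares
    formulation of nonnegative basis pursuit denoising with an adaptive,
    per-dataset regularization parameter. Includes a k-mer training-matrix
    builder, a Lawson-Hanson active-set solver on the augmented system, rank
    -level profile aggregation with L1 (total-error) metrics, a Grinder-style
    WGS read simulator with rank-abundance and error models, an evaluation
    harness with hold-out cross-validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
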