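Package: offsetpack
Title: Compressed Random-Access Offset Arrays for Genomic k-mer Hash Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds lookup hash tables (offset array plus positions array) for
    DNA k-mers and compresses the monotone offset array with block-based
    differential bitpacking designed for random access: a vertical (BP128-style)
    layout with a unidirectional cyclic difference scheme, and columnar layouts
    with a bidirectional difference scheme at block sizes 64 and 32 that reach
    any single value, or any pair of adjacent values, with at most a handful of
    shift/mask/add steps. Block-wise Elias gamma, Elias delta and Fibonacci
    codecs serve as universal-code baselines. A container format with a
    per-block metainformation array (bitstream pointer plus prefix sum) supports
    single-value and one-pass adjacent-pair lookup, file serialization, and
    space/time benchmarking on synthetic genomes and offset arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    utils,
    stats
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
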