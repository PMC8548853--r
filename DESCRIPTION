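Package: poreclass
Title: Raw-Signal Nanopore Read Classification and Read-Until Throughput
    Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies nanopore sequencing reads directly from the raw
    ionic-current signal ("squiggle"), without basecalling or a reference
    database. Provides FAST5 (HDF5) signal input/output, robust
    median-absolute-deviation preprocessing of fixed-length signal windows,
    a compact one-dimensional residual bottleneck network trained with Adam,
    integrated-gradients attribution, a seeded squiggle simulator built on
    k-mer pore models for fully reproducible benchmarking, and a closed-form
    plus Monte-Carlo model of the throughput gained by Read-Until adaptive
    sampling (ejecting non-target molecules after a fixed decision latency).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rhdf5,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    Biostrings,
    optparse,
    jsonlite
Config/testthat/edition: 3
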