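Package: methconsensus
Title: Consensus Calling and Benchmarking of Nanopore CpG Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis toolkit for per-read 5mC CpG calls from
    nanopore methylation callers (Nanopolish, Tombo, DeepSignal, Megalodon,
    Guppy, and per-site DeepMod output). Standardizes the score dialects of
    the individual callers onto a single orientation, aggregates per-read
    calls into per-site methylation frequencies under single- or
    double-threshold cutoff rules, derives data-driven cutoffs from labeled
    reads (Youden, ROC-corner, equal-error band, and rate-bound strategies),
    fits METEORE-style random-forest and ridge-regression consensus models
    over two or more callers, benchmarks callers on controlled
    methylated/unmethylated read mixtures, computes concordance statistics
    against whole-genome bisulfite sequencing replicates, analyses 8-mer
    sequence-context biases, and ships a synthetic-data generator that
    emulates caller score distributions for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    Biostrings,
    ranger,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
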