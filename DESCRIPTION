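Package: rangekit
Title: Fast Genomic Interval Joins on Tidy Data Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A genomic-interval engine for tabular data. Interval tables
    (tibbles with chrom/start/end columns plus arbitrary payload) are joined
    with augmented-interval-list indexes built per contig: overlap joins,
    nearest-feature joins, per-interval overlap counts, and per-interval
    coverage. Both 0-based half-open (BED) and 1-based closed (GFF3/VCF)
    coordinate conventions are supported with explicit conversion. An
    out-of-core streaming executor runs any operation with the probe side
    consumed in bounded batches while only the build side is materialized.
    Includes readers for BED, GFF3 and VCF, a deterministic synthetic-interval
    generator for benchmarking-shaped fixtures, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr (>= 1.1.0),
    tibble,
    readr,
    rlang,
    generics,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    IRanges,
    S4Vectors,
    withr,
    jsonlite
Config/testthat/edition: 3
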