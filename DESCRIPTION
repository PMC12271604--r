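Package: svcompare
Title: Structural Variant Benchmarking with Local Joint Analysis
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Benchmarks structural variant (SV) callsets against a curated
    benchmark VCF. Calls are classified as true positives, false positives,
    false negatives or latent positives using five matching criteria (SV type,
    reference distance, overlap, size similarity and relief-factor weighted
    Needleman-Wunsch sequence similarity), allele-aware best-match selection,
    minimizer-anchored alignment for large variants, and a local joint
    analysis step that validates groups of adjacent small calls as equivalent
    to one larger benchmark variant. Reports size-stratified recall,
    precision and F1, breakpoint-deviation statistics and multi-callset
    true-positive overlaps, and ships a seeded synthetic-data generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    VariantAnnotation,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
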