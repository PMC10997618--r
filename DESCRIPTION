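Package: diphase
Title: Haplotype-Aware Error Correction and Diploid String-Graph Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale diploid genome assembly toolkit for long noisy
    reads. Implements haplotype-aware error correction on partial-order
    alignment (POA) graphs with supporting-read selection and re-weighting,
    a fast string-graph assembler with overhang/contained/low-coverage
    overlap filtering, transitive-edge marking, identity thresholding and
    dead-end repair, a read-level SNP caller with centroid-based
    divide-then-combine read grouping for identifying inconsistent
    overlaps, a second assembly round emitting primary/alternate or dual
    haplotype contigs, trio-binning style evaluation utilities, and a
    built-in synthetic diploid read simulator so that every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    data.table,
    Biostrings,
    methods,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
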