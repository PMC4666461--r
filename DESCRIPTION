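Package: gctsig
Title: Copy-Number-Guided Outcome Signatures for Germ Cell Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrated copy-number and expression analysis for outcome
    prediction in non-seminomatous germ cell tumors. Segments array-CGH
    log-ratio profiles by circular binary segmentation, calls per-clone
    gains and losses, scans clones for outcome association with Fisher's
    exact test, aggregates significant clones into genomic regions by a
    proximity rule, nominates dosage-driven target genes with a
    permutation-based differential-expression screen and directional
    fold-change filters, builds a nearest-shrunken-centroid outcome
    classifier with cross-batch median-matching normalization, and
    evaluates survival separation of predicted groups. Includes a
    synthetic-cohort generator with planted alterations and full ground
    truth for end-to-end benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
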