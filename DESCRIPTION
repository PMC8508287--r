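Package: polyTI
Title: Polysome-Profiling Translatome Analysis and Drug-Combination Synergy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for polysome-profiling RNA-seq experiments
    contrasting polysomal and cytoplasmic mRNA fractions between treated and
    non-treated cells. Computes a per-gene Translational Index (the
    polysomal-to-cytoplasmic ratio in treated over non-treated cells) with
    permutation-based significance and Benjamini-Hochberg FDR, classifies
    translational and transcriptional regulation and cross-tabulates the two,
    calls the 5' terminal oligopyrimidine (5'TOP) motif on 5'UTR sequences
    with hypergeometric set enrichment, and scores drug-combination synergy
    against a Loewe-additivity expectation built from fitted Hill
    dose-response curves. A negative-binomial count simulator and dose-surface
    simulator generate fully specified synthetic inputs so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
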