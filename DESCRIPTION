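Package: emtsig
Title: Derivation of a Prognostic Epithelial-Mesenchymal Transition Gene
    Signature in Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to derive and audit a breast-cancer
    epithelial-to-mesenchymal transition (EMT) gene signature by combining a
    consensus filter over independent EMT gene lists, a tumour-versus-normal
    Welch differential-expression screen, an optimal-cutpoint Kaplan-Meier
    log-rank screen across three survival endpoints (DMFS, OS, RFS) with
    permutation adjustment of the minimum p-value, and a direction-concordance
    intersection of the diagnostic and prognostic calls.  A companion
    proteomic-phenotype module normalises Western-blot densitometry panels to
    a housekeeping channel, computes pairwise Pearson marker correlations,
    and classifies patients into epithelial, hybrid, and mesenchymal states
    from marker ratios.  Synthetic-data generators with the statistical
    structure the analysis assumes (log-normal expression, proportional
    hazards, a three-component marker mixture) make every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
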