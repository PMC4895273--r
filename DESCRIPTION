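Package: rsaboost
Title: Gradient Boosted Regression Trees for Protein Relative Solvent
    Accessibility Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts per-residue relative solvent accessibility (RSA) of
    proteins from sequence-derived features with gradient boosted regression
    trees under a Huber loss. Includes parsers for PSI-BLAST ASCII PSSM,
    PSIPRED .ss2, DISOPRED disorder and DSSP files, a sliding-window feature
    encoder (PSSM, secondary structure, disorder, side-chain environment,
    conservation), RSA labelling from DSSP accessibilities via a Gly-X-Gly
    maximum-accessibility table, real-value and two-state evaluation metrics,
    a protein-level cross-validation and grid-search pipeline, and a
    deterministic synthetic-fixture generator so the whole stack is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    seqinr,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
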