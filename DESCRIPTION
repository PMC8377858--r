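Package: pegforge
Title: Prime Editing pegRNA Design and Efficiency Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates candidate pegRNA/ngRNA combinations for a desired
    genomic edit (SNV, insertion or deletion), extracts the 23 sequence,
    position and RNA-folding features associated with prime-editing
    efficiency, and trains or applies gradient-boosted regression models of
    editing efficiency under grouped nested cross-validation. Includes a
    McCaskill-style partition-function engine for pegRNA base-pair
    probabilities and scaffold-disruption scoring, SHAP-based feature
    attribution, a batch design pipeline with deterministic ranking, and a
    synthetic-data generator for end-to-end testing without external
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    Biostrings,
    vcfR,
    xgboost,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
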