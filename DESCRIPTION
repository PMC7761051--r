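Package: promdiag
Title: Diagnostic Machine Learning for Compound Promiscuity Analysis
Version: 0.1.0
Authors@R:
    person("promdiag", "maintainers", email = "maintainers@promdiag.org",
           role = c("aut", "cre"))
Description: Tools for analysing single- versus multi-target activity of
    biological screening compounds. Builds ternary (active/inactive/untested)
    compound-target activity matrices, curates assays and interference-flagged
    compounds, samples multi-target compounds (MT-CPDs) with matched
    single-target compounds (ST-CPDs) under strict data-completeness rules,
    profiles nearest-neighbor Tanimoto similarity, and runs diagnostic
    machine learning (k-NN, random forest, and support vector machines with a
    Tanimoto kernel) under full, random-removal, and nearest-neighbor-removal
    dataset conditions using double cross-validation. Includes a synthetic
    screening-data generator with planted analog-series structure for
    end-to-end validation, analog-relationship statistics, and shared-compound
    target networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: python (>= 3.8) with scikit-learn for the RF/SVM
    backend and RDKit for SMILES fingerprinting/fragmentation (optional for
    the precomputed-fingerprint workflow).
Config/testthat/edition: 3
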