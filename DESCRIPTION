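Package: cypscreen
Title: Ligand-Based Virtual Screening for Dietary CYP3A4 Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for discovering dietary inhibitors of
    cytochrome P450 3A4 by ligand-based virtual screening. Curates
    dose-response bioassay records into active/inactive labels, trains a
    molecular-fingerprint classifier that emits a prediction index in [0, 1],
    gates predictions with a Tanimoto-distance applicability domain, screens
    compound libraries at a configurable index threshold, flags candidate
    intestine-local inhibitors by Lipinski rule-of-five violations, and
    estimates IC50 values from fluorescence dose-response data by
    four-parameter logistic regression. Ships a fully reproducible
    synthetic-data generator with a planted structure-activity rule for
    benchmarking every stage. Structure handling (canonical SMILES,
    descriptors, fingerprints) is delegated to OpenBabel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    Matrix,
    minpack.lm,
    nnet,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel (>= 3.0, the 'obabel' executable on PATH)
Config/testthat/edition: 3
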