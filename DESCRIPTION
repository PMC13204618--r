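Package: wsisurv
Title: Attention-Based Multiple-Instance and Patch-Level Cox Survival
    Modelling for Whole-Slide Image Embedding Bags
Version: 0.1.0
Authors@R:
    person("wsisurv", "maintainers", email = "wsisurv@example.org",
           role = c("aut", "cre"))
Description: Survival prediction from histopathology whole-slide images
    represented as bags of patch-level feature embeddings. Implements two
    paradigms: an attention-based multiple-instance learning (MIL) model
    trained end-to-end under the Cox partial-likelihood objective, and a
    patch-level Cox baseline in which every patch inherits its slide's
    survival label and slide risk is the mean patch risk. Ships the full
    evaluation pipeline (fold-wise risk standardization, Harrell's C-index,
    Kaplan-Meier quantile stratification, binary-group hazard ratios,
    IPCW cumulative/dynamic time-dependent AUC, bootstrap C-index
    comparison), slide bookkeeping (tile grids, tumor-area exclusion,
    tissue-quality CNN), a synthetic whole-slide cohort generator with
    controllable prognostic signal, censoring and cross-cohort domain
    shift, and scenario runners for cross-validation, cohort transfer and
    combined-cohort experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
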