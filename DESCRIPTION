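Package: irgpi
Title: Immune-Related Gene-Pair Prognostic Index Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Constructs rank-based immune gene-pair prognostic signatures from
    expression and survival data, scores single samples platform-independently
    via within-sample expression-order indicators, stratifies patients into
    risk groups, and evaluates prognostic performance with Kaplan-Meier and
    log-rank statistics, multivariate Cox models, Harrell's concordance index
    with resampling, IPCW time-dependent ROC/AUC, and restricted mean survival
    time ratios. Includes a multi-platform survival-cohort simulator with known
    pair-driven hazard for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    rlang,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
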