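Package: ieegnet
Title: Structural and Effective Intracranial EEG Network Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and compares structural (tractography-derived) and effective
    (single pulse electrical stimulation derived) brain networks anchored on
    intracranial EEG electrode contacts. Provides electrode contact-area
    construction on a grey-white matter boundary mask, streamline-density
    structural networks, cortico-cortical evoked potential detection and
    bi-directional effective networks, inter-modal similarity statistics
    (Jaccard index, expected Jaccard under density-matched chance, permutation
    test, symmetric-difference ratio), node-level topology metrics, and a
    random-intercept multilevel model with backward elimination. A synthetic
    data generator with planted ground truth makes every stage verifiable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    lmerTest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
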