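Package: screentree
Title: Tree-Structured Adaptive Combination of Psychological Screening Scales
Version: 0.1.0
Authors@R: person("screentree", "maintainers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: Builds optimized combinations of comprehensive (multi-symptom)
    and single-assessment psychological screening scales. Historical positive
    diagnosis data yield first- and second-order probability indices that
    reorder symptom blocks and confirmation items; a depth-two scale tree links
    each comprehensive symptom block to its single-assessment scale; and a
    two-tier sequential decision engine administers the tree adaptively with
    early stopping. Includes a synthetic clinical respondent simulator
    (severity mixtures, comorbidity coupling, annotation noise), a
    double-stratified k-fold evaluation harness with macro-averaged metrics,
    ablation variants of the engine, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
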