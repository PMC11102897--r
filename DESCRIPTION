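Package: crowdlaw
Title: Wisdom-of-the-Crowd Label Aggregation with Training-Performance Weighting
Version: 0.1.0
Authors@R:
    person("crowdlaw", "developers", email = "crowdlaw@example.org", role = c("aut", "cre"))
Description: Tools for aggregating crowdsourced multiclass image labels into
    consensus decisions. Implements simple (plurality) voting, top-r expert
    selection by training accuracy, simple accuracy weighting, and a family of
    Bayesian log-accuracy weighting rules built on annotator confusion matrices
    (equal off-diagonal, group-level, and individual-level variants), with
    optional class-prevalence priors, for the seven-class skin-lesion labelling
    setting. Includes annotator profiling from a training split, four evaluation
    metrics (accuracy, balanced accuracy, mean one-vs-rest ROC-AUC, malignant
    ROC-AUC), bootstrap comparison of aggregation rules, crowd-size curves, a
    full selection-by-weighting switchboard analysis, and a synthetic crowd
    simulator with heavy-tailed participation correlated with skill for
    end-to-end testing without access to the original decision data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
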