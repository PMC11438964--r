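Package: stimdyn
Title: Switched-Linear and Bilinear Dynamical Modeling of Stimulation-Evoked
    Intracranial EEG
Version: 0.1.0
Authors@R:
    person("stimdyn", "developers", email = "stimdyn@example.org",
           role = c("aut", "cre"))
Description: Predictive modeling of multichannel intracranial EEG responses to
    direct electrical stimulation. Implements a family of one-step-ahead
    autoregressive models with exogenous pulse-train input -- linear ARX/VARX,
    switched-linear, amplitude-weighted switched-linear, and fully bilinear
    variants -- estimated by ridge regression, together with hierarchical
    model order selection, win-rate and Wilcoxon-based model comparison,
    bootstrap tests of direct and network-mediated causal effects,
    distance-resolved network-interaction profiling with backward elimination
    and sigmoid summaries, and frequency-subset / cross-session
    generalization experiments. A synthetic-data module generates
    ground-truth switched network systems with factorial pulse-train
    stimulation schedules so that every stage of the pipeline is testable
    against known answers.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
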