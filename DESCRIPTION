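Package: egssa
Title: Enhanced Sparrow Search Optimization of Kernel Extreme Learning Machines
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Swarm-intelligence hyperparameter tuning for kernel extreme
    learning machine (KELM) classifiers on clinical tabular data. Implements
    the sparrow search algorithm (SSA) and an enhanced variant (EGSSA) that
    adds hunger-state producer foraging, an exploration/exploitation balance
    factor, and greedy Cauchy perturbation of the incumbent; a 23-function
    box-constrained benchmark suite; confusion-matrix metrics (accuracy,
    sensitivity, specificity, Matthews correlation); cross-validated
    self-adaptive tuning of the KELM kernel width and regularization
    coefficient; and paired Wilcoxon signed-rank comparison of optimizers,
    together with a synthetic tabular disease-data generator so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
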