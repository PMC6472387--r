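Package: penaltygp
Title: Gaussian-Process Policy and Value Analysis for a Continuous Penalty-Shot Game
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a continuous, zero-sum penalty-shot video game between a
    shooter (puck) and a goalie (bar), reduces shooter trajectories to
    change-point decisions, and models the instantaneous switching policy and
    action values with sparse variational Gaussian-process probit
    classification under an automatic-relevance-determination kernel.
    Provides gradient-based, uncertainty-normalised sensitivity indices of the
    latent policy, an exact ANOVA-style variance decomposition of those indices
    into participant, trial, and residual components with a permutation null,
    and final-move expected-value and optimal-timing analyses that contrast
    positioning against timing explanations of skill.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    pracma,
    pROC,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    kernlab,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
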