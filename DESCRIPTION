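Package: reachclust
Title: Model-Based Clustering of Reaching Kinematics and
    Exploration-Exploitation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying exploration and exploitation in reward-based
    motor learning from movement kinematics. Simulates labelled functional
    datasets and synthetic reward-based reaching sessions, converts
    trajectories to fixed-length feature vectors, fits Gaussian mixture
    models by multi-restart expectation-maximization with BIC/AIC model
    selection (first-plateau rule), quantifies trial-to-trial exploration
    versus exploitation (EER, transition matrices, reward-conditioned
    measures), and validates the whole chain with a bootstrap agreement
    study (Adjusted Rand Index, matched-assignment percentage).
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
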