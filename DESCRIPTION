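Package: mbshift
Title: Describing and Anticipating Abrupt Shifts in Microbiome Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing densely sampled microbial community time
    series with the aim of describing and anticipating abrupt compositional
    shifts. Covers spike-in (internal standard) calibration of amplicon read
    counts to absolute 16S rRNA copy concentrations, a windowed Bray-Curtis
    "abruptness" statistic, pairwise maximum-entropy (Ising-type) energy
    landscapes over binary community states with energy-gap and
    stable-state-entropy warning indices, empirical dynamic modeling (Takens
    embedding, simplex projection, S-map forecasting, convergent
    cross-mapping and Jacobian-based local Lyapunov / structural stability),
    ROC/Youden diagnostic thresholding of warning signals, and a generalized
    Lotka-Volterra microcosm simulator with multinomial sequencing-read
    emulation for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    zoo,
    jsonlite,
    tibble,
    dplyr,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
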