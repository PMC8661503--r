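Package: cyclekin
Title: Cell-Cycle Kinetics and Neurogenic Exit of Cycling Progenitor Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimation of cell-cycle length and S-phase length from
    cumulative S-phase-labeling (EdU/BrdU) experiments via the linear
    growth-fraction model, computation of the pulse-chase cell-cycle-exit
    (quit) index from marker x EdU x Ki67 count tables, and
    negative-control-gated flow-cytometry differentiation timecourses.
    Includes an agent-style simulator of asynchronously cycling,
    differentiating progenitor populations so that every estimator can be
    validated by parameter recovery, plus the normality/variance-gatekept
    group-comparison procedure (Shapiro-Wilk, Levene, t/ANOVA/Tukey with
    rank-based fallbacks) used to compare experimental conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    car,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
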