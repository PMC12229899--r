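Package: rewardremap
Title: Reward-Relative Remapping Analysis for Hippocampal Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for hippocampal population recordings in
    virtual-reality reward-switch tasks. Simulates sessions with known
    ground-truth tuning classes, identifies place cells by spatial
    information with circular shuffles, classifies remapping with respect
    to the reward zone versus the spatial environment, quantifies
    behavioral-timescale sequences with circular-circular correlation,
    decodes reward-relative position, fits a Poisson encoding model with
    variable ablation, warps trials on speed profiles, and detects
    trial-resolved remap times with factorized k-means distance scores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    splines,
    glmnet,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
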