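Package: leverseq
Title: Analysis of Self-Paced Serial-Order Lever-Press Sequences and
    Peri-Event Neural Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for operant serial-order sequence experiments in which
    animals chain two subsequences of lever presses (at least four presses
    on lever 1 followed by at least four on lever 2). Parses timestamped
    behavioral event logs into trials with a full error taxonomy (incorrect
    start, subsequence breaks, premature switches), computes timing metrics
    (latency to start, sequence duration, transition time, inter-press
    intervals), converts spike trains to kernel-smoothed instantaneous
    firing rates, aligns and z-scores activity around press anchors,
    linearly time-rescales trials onto a canonical sequence template, and
    detects modulation with sliding-window AUROC permutation maps,
    covariate-binned permutation regression and a z-difference test across
    unit populations. Includes estimation statistics for state-dependent
    optogenetic on/off designs (paired and unpaired permutation t tests,
    bootstrap confidence intervals, Benjamini-Hochberg FDR), antidromic
    photo-identification criteria, and a synthetic-session simulator with
    programmable behavioral error rates and inhomogeneous-Poisson spike
    modulation for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
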