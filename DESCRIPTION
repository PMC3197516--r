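Package: cprflow
Title: No-Flow Time and Ratio Analysis for Resuscitation Event Logs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes cardiopulmonary-resuscitation quality metrics from
    timestamped event logs of cardiac-arrest scenarios: no-flow time (NFT)
    and no-flow ratio (NFR), guideline-allowance-adjusted variants that
    credit sanctioned pauses for rhythm analysis, shock delivery and pulse
    checks per two-minute advanced-life-support cycle, compression rates,
    30-second no-flow segment profiles, and time-to-event markers, split
    between a first-responder phase and a cardiac-arrest-team phase.
    Includes SPSS-compatible median/interquartile cohort summaries, an
    exact two-sided Mann-Whitney U test for small samples, a calibrated
    discrete-event simulator of unannounced in-hospital arrest scenarios
    for validation with known ground truth, and a command-line pipeline
    (generate, analyze, selftest).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
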