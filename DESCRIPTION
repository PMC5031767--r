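Package: toogood
Title: Test for Excess Success via Simulated Replication of Multi-Test
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to ask whether a set of reported experiments is "too
    good to be true". Given a declarative description of an experiment's
    population model (per-condition sample sizes, means, standard
    deviations and within-subject correlations) and a success criterion
    (the conjunction of significant and non-significant test outcomes
    that the original claims rest on), the package simulates direct
    replications, estimates the probability that the full pattern of
    outcomes recurs, sweeps sample sizes to find the attainable ceiling
    on that probability, and multiplies probabilities across independent
    studies to flag experiment sets whose uniform success is implausible
    under honest sampling. Closed-form noncentral-t power calculations
    provide a fast path and an independent oracle for the Monte-Carlo
    engine.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    parallel,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
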