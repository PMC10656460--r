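Package: chainaccel
Title: Anchor Chaining with Bounded Lookback and Prediction-Based
    Accelerator Scheduling
Version: 0.1.0
Authors@R:
    person("chainaccel", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Co-linear anchor chaining for long-read sequence mapping, with
    the bounded-lookback and sub-partitioned dynamic-programming variants
    used by fixed-trip-count hardware accelerators. Includes a synthetic
    anchor-set generator with planted chains, minimizer-based anchor
    extraction from FASTA, linear-regression predictors of per-task
    hardware and software chaining time, a discrete-event simulator of a
    prediction-based CPU/accelerator task-placement policy with per-kernel
    FIFO queues, and chain-level concordance analysis between bounded and
    exact chaining.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
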