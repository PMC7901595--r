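Package: pathoconcord
Title: Hierarchical Bayesian Analysis of Digital Pathology Diagnostic Concordance Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for multi-rater diagnostic concordance studies of the kind
    used to evaluate transitions from glass-slide to digital (whole slide
    imaging) pathology. Provides validated item-level data structures and
    delimited-text input/output, a synthetic-study generator emulating a
    factorial design of raters, cases and conditionally eligible diagnostic
    tasks, descriptive error-rate analytics (per-group tables, median/IQR
    summaries, cross-tabulated raw proportions), a hierarchical
    varying-intercepts Bernoulli model on the logit scale fitted by a built-in
    No-U-Turn Hamiltonian Monte Carlo sampler with centered and non-centered
    parametrizations, prior and posterior predictive simulation of rater
    performance by career level with highest-posterior-density intervals, and
    Likert-scale survey aggregation. An item-level dataset can also be
    reconstructed from published marginal error-count tables by seeded
    greedy assignment with repair passes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rjags,
    withr,
    optparse
Config/testthat/edition: 3
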