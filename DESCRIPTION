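Package: htuAlloc
Title: Harm-Threshold Utilitarian Organ Allocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements harm-threshold utilitarianism (HTU), a sequential
    organ-allocation decision rule that maximizes uncertainty-adjusted
    post-transplant benefit subject to an epistemic confidence screen and a
    catastrophic-harm protection step, together with the apparatus needed to
    study it: comparator policies (MELD-max, unconstrained utilitarian), a
    synthetic transplant-candidate cohort generator, a Monte-Carlo offer-pool
    simulator, Kaplan-Meier and restricted-mean-survival-time outcome
    evaluation, harm-threshold sensitivity frontiers, and rank-concordance
    analysis between MELD and HTU priority orders. A command-line interface
    binds the pieces into reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
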