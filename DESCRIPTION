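Package: canmpt
Title: Individual-Level Scoring and Multinomial Processing Tree Models for
    Moral Dilemma Batteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for four-cell moral-dilemma batteries that cross norm type
    (proscriptive vs. prescriptive) with consequence type (benefits greater
    vs. smaller than costs). Computes closed-form individual-level scores for
    consequence sensitivity (C), norm sensitivity (N) and overall action
    preference (A) from the four cell action probabilities, and fits the
    CNI, NCI and DNA multinomial processing trees to aggregated cell counts
    by maximum likelihood with G-squared goodness of fit and
    delta-G-squared likelihood-ratio constraint tests. Includes a
    synthetic-population simulator for parameter-recovery and calibration
    studies, group-comparison and trait-correlation reports contrasting the
    tree-model and algebraic scoring frameworks, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
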