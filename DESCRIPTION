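Package: mrfocus
Title: Focused Instrument Selection and Post-Selection Inference for
    Two-Sample Summary-Data Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("mrfocus", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Causal-effect estimation for two-sample summary-data Mendelian
    randomization when an investigator trusts only a core subset of genetic
    instruments. Provides limited information maximum likelihood (LIML)
    estimation over the core and full instrument sets under many weak
    instruments, selection between them by estimated asymptotic mean squared
    error (AMSE), and post-selection confidence intervals: the standard,
    naive, 1-step and 2-step constructions, and a focused interval that
    bounds the worst-case asymptotic coverage loss by a user-chosen size
    distortion. Includes a simulation harness generating summary data with
    concentration-parameter-calibrated instrument strength and locally
    invalid direct effects, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
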