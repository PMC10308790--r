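Package: ccpower
Title: Power, Expected P-Values and Detectable Odds Ratios for
    Case-Control Studies with Many Controls per Case
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Design calculations for case-control association studies that
    test many hypotheses at small type-1 error, where recruiting well beyond
    the classical 4 controls per case can still pay off.  Provides
    closed-form power transfer across controls-per-case ratios under local
    alternatives, median expected p-values under the alternative, the
    fractional reduction of the minimum detectable odds ratio toward the
    null, an explicit allele-based score-test power model for genome-wide
    association study designs with odds-ratio inversion by root finding,
    Monte-Carlo calibration checks of the asymptotic p-values, and
    order-of-magnitude squaring/doubling rules of thumb.  Reproduces
    reference design tables and emits machine-readable grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
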