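Package: iwqi
Title: Integrated-Weight Water Quality Index and Groundwater Hydrochemistry
Version: 1.0.0
Authors@R: person("iwqi", "developers", role = c("aut", "cre"),
    email = "iwqi-dev@example.org")
Description: Groundwater-quality assessment with the integrated-weight water
    quality index (IWQI): Shannon-entropy subjective weights, stochastic-
    simulation objective weights drawn from a literature weight database,
    preference-coefficient integration, sub-index scoring and five-class
    classification, and index-removal sensitivity analysis.  Also provides
    the supporting hydrochemistry toolkit: charge-balance QC, meq/L
    conversion, Piper trilinear coordinates and facies naming, Gibbs ratios,
    ion-ratio source diagnostics, seasonal descriptive statistics with
    exceedance rates, a truncated-normal synthetic sample generator, CSV
    input/output and a command-line pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
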