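Package: tabletrom
Title: Reduced-Order Tableting Models Coupled to Lubricant and Glidant Mixing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Four-stage reduced-order models (ROMs) of pharmaceutical tablet
    compaction (die filling, Kawakita compaction, elastic recovery and
    Leuenberger tensile strength) whose parameters are bivariate rational
    functions of upstream excipient concentration and blending time. Provides
    the constrained rational-function model library, AIC-based model selection
    with small-sample correction, seeded multi-start constrained least-squares
    estimation, bootstrap confidence intervals, first-order Sobol global
    sensitivity indices, Latin-hypercube campaign design and a forward
    simulator of tableting campaigns for magnesium stearate (lubricant) and
    colloidal silica (glidant) formulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lhs,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
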