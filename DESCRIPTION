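Package: chromoscore
Title: Chromothripsis Scoring and Downstream Structural-Variant Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects chromothripsis from segmented total copy-number profiles
    by counting switches between copy-number states inside a sliding genomic
    window, assigns confidence tiers and canonical/non-canonical labels, and
    runs the downstream analyses that commonly accompany such calls:
    size-matched region permutation tests for per-chromosome enrichment,
    genome walking over structural-variant adjacencies from the TERT locus,
    breakpoint-microhomology binning with beta-regression contrasts,
    fusion-call validation against genomic breakpoints with count-regression
    modelling, and cohort-level association and longitudinal analyses. A
    seeded synthetic cohort generator with a planted-event truth table makes
    the whole pipeline testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
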