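Package: healthrank
Title: Multi-Criteria Priority Setting for Health Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-criteria decision analysis (MCDA) in regional
    health priority setting. Elicits criterion weights from ordered-choice
    public preference surveys by the normalized-sum and rank-order-centroid
    (SMARTER) methods with Hare-Niemeyer largest-remainder rounding, maps raw
    burden-of-disease indicators (DALY share, diminished household income,
    ICER, equity rate ratios, multimorbidity hazard ratios) onto 1-5 impact
    levels, ranks health conditions by a weighted additive composite score,
    and validates rankings against free-text public health concerns via a
    stemmed, stopword-filtered term-document matrix. Includes seeded
    synthetic-data generators so every pipeline stage is testable without
    external data, and a command-line interface for end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
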