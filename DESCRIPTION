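Package: mccen
Title: Multiclass Matthews Correlation, Confusion Entropy, and Their Relation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Performance measures for multiclass classifiers evaluated from
    confusion matrices: accuracy, the multiclass Matthews Correlation
    Coefficient (MCC), the Confusion Entropy (CEN), and the logarithmic
    transform of MCC (tMCC) that approximates CEN and is exact on
    diagonal-plus-constant matrices. Includes closed-form limit-case matrix
    families (uniform off-diagonal, single off-diagonal corner, dice-rolling
    no-information classifiers), Huang-Ling degree-of-discriminancy and
    degree-of-consistency statistics for comparing measures, exhaustive
    enumeration of confusion matrices with fixed per-class counts and of all
    small binary confusion matrices, and seeded Monte Carlo studies of the
    tMCC-CEN relation, with a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
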