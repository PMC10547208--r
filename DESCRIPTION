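Package: mriscore
Title: Adaptation Scores for Identifying Metabolic Reprogramming from
    Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates per-gene expression levels into a genome-scale
    metabolic model and computes an adaptation score: the maximum number
    of measured metabolic genes whose expression can be fully converted
    into steady-state flux. The score is obtained from a mixed-integer
    linear program built on the irreversible, isozyme-expanded form of
    the model, with per-gene expression-usage constraints, big-M usage
    indicators, and direction-exclusivity constraints on reversible
    reactions. Includes conditional scoring with a target reaction or
    gene fixed at its maximal usage, key-gene identification for
    wild-type versus adaptively evolved strain pairs, calibration of the
    expression-to-flux conversion constant against measured growth
    rates, SBML import/export, a deterministic toy-model and expression
    profile generator, and an exhaustive-enumeration oracle for
    validating solver results on small instances. Mixed-integer programs
    are solved with the HiGHS solver through the Python 'scipy' stack.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    quadprog,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with numpy and scipy (>= 1.9) on the
    PATH as 'python' or 'python3'.
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
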