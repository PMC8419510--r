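Package: whoselect
Title: Wildebeest Herd Optimization for Wrapper Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A feature-selection toolkit built around the Wildebeest Herd
    Optimization (WHO) metaheuristic. Provides WHO as a general box-bounded
    continuous minimizer, a wrapper feature-subset selector driven by
    cross-validated classifier error, tree-ensemble Gini-importance and
    chi-square pre-filters, the diagnostic metric suite used in binary
    melanoma screening (accuracy, sensitivity, specificity, Dice, PPV, NPV),
    repeated-run fitness statistics, a synthetic generator emulating
    high-redundancy deep-feature matrices, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
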