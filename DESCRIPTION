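Package: lrcde
Title: Cell Type-Specific Differential Expression by Linear Regression
    Deconvolution
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Deconvolves heterogeneous (bulk) gene expression into cell
    type-specific expression estimates by per-group, per-gene no-intercept
    least squares on measured cell proportions, and tests cell
    type-specific differential expression with per-gene Welch t-tests.
    Reports effect sizes, p-values, t-statistic-based detection power,
    group-specific mean squared error, and condition-number diagnostics of
    the proportion design matrix. Includes a controlled simulator of
    sum-to-one cell proportions with a target cell-proportion standard
    deviation and design-matrix condition number, a permutation cut-point
    false discovery rate comparator, and drivers for sensitivity
    benchmarking experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
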