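Package: mrsplit
Title: One-Sample Mendelian Randomization with Adaptive Sample Splitting
    and Cross-Fitted Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Causal-effect estimation for one-sample Mendelian randomization
    with individual-level genotype, exposure and outcome data.  Instruments
    are selected within half-samples by sure independence screening followed
    by (debiased) LASSO, classified into major and weak instruments with a
    partial F-statistic threshold, and the weak instruments are consolidated
    into a sign-preserving composite instrument built on the opposite
    half-sample.  Cross-fitted exposures feed a two-stage least-squares
    second stage, and results from many random splits are aggregated with
    the Cauchy combination rule.  Comparator estimators (two-stage least
    squares, limited-information maximum likelihood, and cross-fitted MR
    with a single polygenic-score instrument) and a Monte-Carlo simulation
    harness for bias, coverage, type-I error and power studies are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
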