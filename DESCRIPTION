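Package: survsvr
Title: Support Vector Regression for Right-Censored Survival Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Support vector regression (SVR) models for right-censored
    survival data: a standard censored SVR with asymmetric constraints, a
    variant with ranking constraints over comparable pairs, and a two-sided
    model that augments each censoring time with its Kaplan-Meier mean
    residual lifetime. Includes linear, polynomial, RBF and clinical
    additive kernels, survival performance measures (Harrell's concordance
    index, two-group log-rank statistic, median-split hazard ratio),
    three-fold cross-validation tuning, a repeated random-split benchmark
    harness with a Cox proportional hazards baseline, SVR-based feature
    selection (association tests, univariate concordance ranking, recursive
    feature elimination), and a simulator for exponential event/censoring
    times driven by sparse linear predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    quadprog,
    survival,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
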