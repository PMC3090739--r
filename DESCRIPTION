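Package: optsplit
Title: Optimal Training/Test Allocation for High-Dimensional Classifier Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding how many samples of a high-dimensional
    (e.g. gene-expression) study to allocate to classifier training versus
    independent testing.  The mean squared error of the hold-out accuracy
    estimate is decomposed into an accuracy-variance term, a binomial-variance
    term and a squared-bias term, and evaluated over a grid of candidate
    training-set sizes.  A parametric simulation engine built around the
    compound covariate predictor maps two-class multivariate-normal scenarios
    to optimal splits, and a nonparametric resampling algorithm recommends the
    optimal split for a specific dataset with any plug-in classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
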