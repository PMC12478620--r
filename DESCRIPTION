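Package: pklm
Title: Projected Kullback-Leibler Test for Missing Completely at Random
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Nonparametric, permutation-based test of the missing-completely-at-random
    (MCAR) hypothesis for an incomplete data matrix with mixed numeric and
    categorical columns. Random projections of the variable set define multiclass
    classification problems whose labels are collapsed missingness patterns; a
    probability random forest with out-of-bag predictions yields a symmetrized
    log-odds statistic that estimates a Kullback-Leibler divergence between
    pattern groups. Global row permutations of the missingness matrix give a
    finite-sample valid p-value, and partial p-values localize which variable's
    missingness violates MCAR. Includes generators for a suite of simulation
    distributions and MCAR/MAR amputation mechanisms for level and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
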