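Package: wedgealloc
Title: Optimal Allocation of Observations in Stepped-Wedge and Other
    Cluster Trial Layouts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes optimal allocations of a fixed number of observations
    across the cluster-periods of stepped-wedge, parallel, cross-over, or
    arbitrary discrete-time cluster-trial layouts under a linear mixed model
    with time-varying cluster autocorrelation. Provides the generalized
    least squares (BLUE) variance of the treatment effect for any allocation,
    an alternating optimization algorithm for the optimal design measure,
    best natural allocations (designs whose BLUE is the simple treated-minus-
    control difference of means), closed-form staircase designs with exact
    optimality conditions, index-of-cluster-variation thresholds, and
    efficient rounding of design weights to integer sample sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
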