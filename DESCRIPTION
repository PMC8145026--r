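Package: paretoclust
Title: Pareto Clustering via Kolmogorov-Nagumo Averages of Survival Functions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based clustering built on the Kolmogorov-Nagumo
    (quasi-arithmetic) average of survival functions. The generalized Pareto
    survival function yields a one-family clustering objective whose limiting
    cases are k-means, fuzzy c-means, Gaussian-mixture modelling and
    maximum-entropy (deterministic-annealing) clustering. Provides the
    minorize-maximization (MM) estimator with Ward-linkage initialization,
    ridge-regularized covariance updates and analytic limit modes; the
    underlying heavy-tailed mixture density with a Metropolis-Hastings sampler
    for simulation studies; and external cluster-validation metrics (purity,
    F-value, centroid index, matched center mean squared error).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse,
    yaml
Config/testthat/edition: 3
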