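Package: fmblaw
Title: Force-Metric-Bias Decomposition of Selection and Learning Updates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact Price-equation partitioning of change in weighted
    populations and its force-metric-bias (FMB) re-expression, in which any
    selection or learning update of a mean parameter vector decomposes as
    metric times force plus bias plus noise.  Provides the discrete
    information-geometric quantities tied to that decomposition (Fisher-Rao
    step length, Kullback-Leibler and Jeffreys divergences, square-root
    coordinates, conservation identities), discrete Bayesian updating and
    variational Bayes expressed as selection, a zoo of single-vector
    optimizers (gradient descent, Newton, quasi-Newton, natural gradient,
    mirror descent, regularized and momentum methods, Adam, stochastic
    Langevin and minibatch gradients) each audited against its own FMB
    decomposition, population methods (evolution strategy, Gaussian-process
    mean update, Kalman filter) reduced to metric-times-force form, and the
    recursive two-level Price equation with its hierarchical FMB law.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
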