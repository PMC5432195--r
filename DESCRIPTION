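Package: balancedline
Title: Coupled Balanced Networks with a Line of Balanced States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Event-driven simulation and mean-field analysis of two
    reciprocally inhibiting balanced networks of binary neurons, a model of
    continuous-parameter working memory. Provides the sparse random
    connectivity generator, an asynchronous (Poisson-clock) simulator of the
    binary dynamics, the mean-field theory of the continuum of balanced
    states (fixed points, Jacobians, eigenvalues, and the tuning of the
    mutual inhibition that produces a line attractor), estimators of drift
    and diffusion along the approximate attractor with Ornstein-Uhlenbeck
    fits, spike and population cross-covariance estimators, and a
    semi-analytic prediction of the diffusion from single-network noise
    correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
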