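Package: dspriors
Title: Goodness-of-Fit Empirical Bayes with DS(G,m) Priors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generalized empirical Bayes modelling in which a parametric
    conjugate prior g(theta; alpha, beta) is treated as a testable starting
    hypothesis rather than a fixed assumption.  The package diagnoses
    prior-data conflict through the U-function (the prior density ratio on
    the rank-transform scale) and the qLP uncertainty statistic, corrects the
    conjugate prior nonparametrically with an orthogonal series of
    rank-Legendre polynomials whose coefficients are estimated by an
    iterative method-of-moments algorithm with BIC smoothing, and delivers
    macro-inference (consensus means and modes with smooth-bootstrap standard
    errors) and micro-inference (Elastic-Bayes posterior summaries that
    shrink each study selectively toward relevant modes) for binomial,
    Poisson, normal, and exponential data.  Includes classical comparison
    estimators (Stein parametric empirical Bayes, Robbins' frequency-ratio
    rule for Poisson counts), bundled worked datasets, and synthetic-data
    generators for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, jsonlite, pracma
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
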