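Package: tasteshift
Title: Random-Preference Discounting Models and Bayesian Preference Shift
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models of intertemporal choice in which decision variability
    reflects uncertainty about one's own taste for patience, and a Bayesian
    account of how observing another person's discounting choices shifts that
    taste. Implements the hyperbolic discounting softmax (KT) model, the
    random-preference (KU) model in which the log discount rate is sampled
    from a Gaussian belief on every trial, and the five-parameter
    uncertainty-relevance preference-shift (PS) model in which self- and
    other-beliefs are coupled through a latent reference population.
    Includes a simulator for the three-phase Delegated Interpersonal
    Discounting task with entropy-minimising adaptive trial selection,
    MAP/Laplace and component-wise Metropolis MCMC fitting, a two-pass
    empirical-Bayes scheme, BIC model comparison, and population-level
    statistics (partial correlations, shift regression, mediation by
    partial correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
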