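Package: meristevo
Title: Fossil-Inclusive Macroevolutionary Analysis of Meristic Skeletal Counts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for testing macroevolutionary trend hypotheses (such as
    Williston's law of skeletal simplification) on meristic counts scored for
    extant and extinct species on a time-scaled phylogeny. Provides minimum
    branch-length stratigraphic time-scaling with fossil tip-age resampling,
    exact Gaussian likelihoods and maximum-likelihood fitting for five
    continuous trait models (Brownian motion, Ornstein-Uhlenbeck, early burst,
    Brownian motion with a trend, and white noise), ordered single-step Markov
    models of gain and loss with likelihood-ratio tests, contrast-based model
    adequacy statistics with posterior-predictive p-values, taxon jackknife
    sensitivity analyses over tree ensembles, and a synthetic-data generator
    producing birth-death trees with sampled fossils and count tables so the
    whole pipeline is testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
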