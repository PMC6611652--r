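Package: triadhmm
Title: Belief-State Hidden Markov Model Analysis of Cyclic Triad Operant Behaviour
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing behaviour in a cumulative handling time
    task whose trials follow a deterministic cyclic triad (lead, test, trail).
    Provides a generative simulator for the task schedule and for synthetic
    agents, a recognition model in which past evidence is integrated with
    within-trial observations of pulse frequency and price through a
    belief-transition matrix parameterised by an uncertainty parameter gamma
    and a perceptual kernel width sigma, maximum-likelihood fitting of the
    model and its nested variants with BIC comparison, Hessian-based standard
    errors, and the permutation, binomial-proportion and earth-mover's
    similarity tests used to analyse engagement probabilities and initial
    response times.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
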