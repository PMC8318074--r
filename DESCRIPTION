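Package: valenceddm
Title: Valence-Dependent Drift-Diffusion Modeling of Sequential Evidence Accumulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the desirability of a conclusion shapes
    sequential evidence accumulation in a two-alternative "factory" judgment
    task. Provides a generative simulator of the task (hidden desirable or
    undesirable states, Bernoulli stimulus streams, free response times), a
    two-boundary Wiener diffusion core on the log response-time scale
    (first-passage densities, absorption probabilities, trial likelihoods
    with across-trial starting-point variability, and a path simulator used
    as a brute-force oracle), a four-model family separating starting-point
    bias from a valence-dependent drift-rate bias, hierarchical Bayesian
    estimation by Markov chain Monte Carlo with Gelman-Rubin diagnostics and
    DIC model comparison, logistic psychometric-function fitting, and a
    simulate-fit-recover pipeline with the task's exclusion rules and
    model-free judgment-bias statistics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
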