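Package: limitedoffer
Title: Active-Inference Modelling of the Limited-Offer Waiting Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the limited-offer task -- a finite-horizon sequential
    game in which a small standing offer may be withdrawn or replaced by a
    large offer under trial-varying hazard rates -- as a Markov decision
    problem solved by active inference. Policies (wait until trial k, then
    accept) are scored by the Kullback-Leibler divergence from their predicted
    terminal-state distribution to a desired-outcome distribution, and the
    precision (inverse temperature) of the policy posterior carries a Gamma
    belief with a Bayes-optimal variational update at every trial. The package
    simulates single games and cohorts under interpretable subject-level
    parameters (prior precision, subjective hazard scale, outcome
    sensitivity), provides choice-phenotype presets, records simulated
    dopamine responses as trial-to-trial precision changes, and recovers the
    subject-level parameters from choice data by maximum a posteriori model
    inversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
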