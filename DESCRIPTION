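Package: evacchoice
Title: Dynamic Exit-Route Choice in Simulated Crowd Evacuations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how people choose between two emergency
    exits while a crowd queues in front of them. Provides an agent-based
    simulator of a two-exit room with scripted queueing pedestrians, a
    sixteen-member family of per-time-step logistic exit-choice models
    built from time-independent (exit width, visible route length) and
    time-dependent (queue length, queue flow) information, Bayesian model
    selection by replicated stepping-stone marginal-likelihood estimation
    with Bayes-factor evidence categories, outcome-level binomial GLM and
    exact binomial analyses, and a synthetic-cohort generator with known
    generating parameters for end-to-end recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, tools
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
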