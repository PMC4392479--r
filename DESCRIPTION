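Package: pclicks
Title: Behavioral Modeling of the Poisson Clicks Evidence-Accumulation Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and trial-by-trial likelihood analysis of two-alternative
    choice behavior in the Poisson Clicks task. Generates Poisson click-train
    stimuli and model-driven choices from a nine-parameter bounded stochastic
    accumulator with sensory adaptation, computes exact (to grid tolerance)
    choice probabilities by propagating the accumulator probability density
    between click events, fits the model and its lateralized bias-mechanism
    extensions by maximum likelihood, and provides bootstrap resampling,
    random-walk Metropolis sampling, likelihood surfaces, leave-one-session-out
    cross-validation, information-criterion model comparison, and descriptive
    psychophysics (psychometric and chronometric curves, reverse correlation).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    minpack.lm,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
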