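Package: pavlovhmm
Title: Model-Based and Model-Free Learning Models for Pavlovian
    Serial-Reversal Conditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates probabilistic Pavlovian serial-reversal conditioning
    sessions and fits trial-by-trial learning models to reaction times. The
    package implements a Bayesian hidden Markov learner with a dynamic
    expectation of contingency reversal (and a reduced constant-hazard
    variant), the Rescorla-Wagner, Pearce-Hall and hybrid learning rules, and
    a constant-value baseline. Model expected-value traces are fitted to
    log-transformed, trend- and switch-adjusted reaction times by grid search,
    scored by the Bayesian information criterion, and compared with
    random-effects Bayesian model selection (posterior and exceedance
    probabilities) plus a simulation-based baseline validation combined across
    subjects with Fisher's method.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
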