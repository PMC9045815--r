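Package: seqchoice
Title: Behavioral and Neuronal Analysis of Economic Choice Under
    Sequential Offers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analyzing economic choice behavior and orbitofrontal
    cortex activity in tasks where two goods are offered simultaneously or
    in sequence. Fits probit/logit choice models and derives relative value
    (rho), sigmoid steepness (eta) and order bias (epsilon); quantifies the
    preference bias across tasks by ANCOVA; classifies neurons into offer
    value, chosen juice and chosen value groups via signed-R2 regression
    across time windows; compares tuning functions and activity ranges
    across tasks; derives neuronal measures of relative value from chosen
    value cells; quantifies circuit inhibition and ROC choice probabilities
    in chosen juice cells; and generates synthetic sessions with Poisson
    spike trains emulating all of the above for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
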