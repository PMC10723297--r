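Package: activecall
Title: Belief-Based Simulation and Analysis of Contact-Call Exchanges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates dyadic contact-call exchanges between two Bayesian
    agents that choose call durations either by vocal accommodation
    (sampling from their belief about the optimal duration) or by active
    sampling (sampling from the normalized Expected Information Density,
    the expected Shannon-entropy reduction of the belief for each candidate
    duration). Provides the matching empirical pipeline for vocal-exchange
    session tables: syllable-to-call segmentation, response-window marking,
    Gaussian-mixture clustering of call durations with BIC elbow selection,
    time-binned coefficient-of-variation dynamics with sigmoid fits, and
    bootstrap tests for trends in response proportions, together with a
    synthetic two-caller session generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    mclust,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
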