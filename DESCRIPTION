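Package: voirank
Title: Prioritizing Decision-Model Parameters for Updating and Distributional Adaptation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to decide which inputs of a health-economic decision model
    deserve new evidence. Implements value-of-information analysis (EVPI and
    regression-based EVPPI) on probabilistic sensitivity analysis (PSA) output,
    a greedy conditional-EVPPI ranking with an update metric, and a
    percent-rescaled least-squares semielasticity ranking with an adaptation
    metric for distributional cost-effectiveness work. Ships a configurable
    four-state oncology Markov cohort simulator and a linear-Gaussian toy model
    with closed-form value-of-information quantities for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    mgcv,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
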