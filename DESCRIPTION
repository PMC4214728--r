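Package: herdfate
Title: Capture-Recapture Survival, Herd Demography and Sustainability
    Breakpoints for Managed Reindeer Herds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for diagnosing collapse in free-ranging, managed reindeer
    herds from individual mark-recapture records and herd-level count and
    harvest statistics. Implements the Cormack-Jolly-Seber model for live
    recaptures with an m-array multinomial likelihood, constrained maximum
    likelihood fitting on the logit scale with fixed and boundary parameters,
    Wald confidence intervals and AICc model comparison; herd-level growth,
    recruitment and harvest rates plus annualized and accumulated female
    survival; and a female-only Leslie matrix solver for the maximum
    sustainable adult mortality (the mortality at which the dominant
    eigenvalue reaches one) under alternative calf-survival scenarios. A
    synthetic-data generator reproduces the sampling design of a two-herd,
    multi-year monitoring programme so the whole pipeline is testable
    without access to the original individual records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
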