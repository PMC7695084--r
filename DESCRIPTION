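Package: trachomacost
Title: Financial Cost Model for Trachoma Impact Survey Decisions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost model comparing two strategies for
    trachoma elimination programs at the evaluation-unit (EU) level:
    (a) conduct an impact survey and continue antibiotic mass drug
    administration (MDA) only where the prevalence of trachomatous
    inflammation-follicular (TF) remains at or above 5 percent, versus
    (b) continue MDA for another year without surveying. Provides the
    closed-form break-even continuation rate, a population-elasticity
    model of MDA unit costs, a scenario grid across EU population sizes,
    a portfolio case-study engine for retrospective per-EU accounting
    (with the United Republic of Tanzania 2017-2018 programme table
    shipped as a fixture), and a seeded synthetic-portfolio generator
    that validates the closed-form break-even rate by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
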