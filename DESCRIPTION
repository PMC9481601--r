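Package: pvlung
Title: Disproportionality and Time-to-Onset Analysis for Spontaneous
    Adverse-Event Report Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection in JADER-style
    spontaneous adverse-event reporting databases. Reads, deduplicates and
    merges demographic (DEMO), drug (DRUG) and reaction (REAC) tables into a
    suspected-drug analysis table; screens drug-event pairs with the
    reporting odds ratio (ROR), Woolf confidence intervals and Fisher's
    exact test; computes time-to-onset samples under partial-date and
    dosing-gap rules and fits two-parameter Weibull models whose shape
    parameter classifies the hazard as early, random or wear-out failure;
    tabulates post-event outcomes; and simulates report databases with
    planted drug-event associations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    survival,
    optparse,
    withr
Config/testthat/edition: 3
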