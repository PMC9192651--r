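Package: suidbn
Title: Bayesian Network Decision Models for Sudden Unexpected Infant Death
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete Bayesian-network decision models supporting the
    categorization of sudden unexpected infant death (SUID). Provides a small
    exact-inference engine (conditional probability table estimation,
    enumeration and variable elimination), diagnostic support models that
    classify deaths as SIDS versus other internal or external causes, an
    age-stratified onset-predictive model that updates a population SIDS
    incidence prior with case-versus-population likelihood ratios, regional
    SUID-classification variability statistics (coefficient of variation),
    and seeded synthetic-data generators (marginal-exact replicate cohorts,
    ancestral sampling, regional surveillance counts) so the whole pipeline
    is testable without access to the original forensic case data.
License: MIT + file LICENSE
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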