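Package: agesirs
Title: Eco-Evolutionary Dynamics of Pathogens in Age-Structured SIRS Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying pathogen evolution in host populations divided
    into discrete age stages with stage-specific demography. Implements an
    age-structured susceptible-infected-recovered-susceptible (SIRS)
    compartmental model, a two-strain resident/mutant extension with total
    cross-immunity, next-generation-matrix computation of the basic
    reproduction number R0 and of the mutant invasion number Q0 (including a
    closed-form trace formula for rank-one transmission matrices), solution of
    the evolutionarily stable strategy (ESS) condition under a concave
    infectivity-recovery trade-off, and evolutionary invasion-replacement
    simulations with sensitivity modes for non-separable contact matrices and
    high case-fatality regimes. Scenario configurations are read and written
    as YAML; a thin command-line driver is included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
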