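Package: epirescue
Title: Evolutionary Rescue with Partly Heritable Phenotypic Variability
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Birth-death models of evolutionary rescue for populations in
    which a mutant allele expresses a variable, partly heritable phenotype
    (stochastic phenotype switching / bet-hedging). Provides closed-form and
    quadrature approximations for the epimutation-selection balance, the
    effective birth rate of the variable lineage, and establishment and
    rescue probabilities after an abrupt environmental change (de novo
    mutation entering with the beneficial or the deleterious phenotype, and
    standing variation); an exact continuous-time (Gillespie) simulator
    supporting periodic environments, density-dependent birth rates, multi-
    point phenotype distributions and a linked resistance locus; and
    ensemble drivers for rescue-probability curves, mean-extinction-time
    sweeps and resistance-epistasis comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, stats, utils, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
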