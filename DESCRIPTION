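Package: marinerkin
Title: Kinetic Models of Strand Cleavage by the Mariner Transpososome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the excision of a mariner (Hsmar1) mini-transposon from a
    supercoiled plasmid as a continuous-time Markov chain over discrete
    per-end cleavage states, under three competing mechanisms for the order
    of strand cleavage at the two transposon ends (independent, sequential,
    constrained). Provides deterministic master-equation and Gillespie
    simulation of species time courses, a virtual restriction digest and
    end-labeling readout that predicts denaturing-gel band tables, a
    synthetic quantified-gel data generator with multiplicative lognormal
    noise, and a maximum-likelihood fitting and AIC model-selection pipeline
    that discriminates the constrained cleavage order from time-course data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
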