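Package: recfreq
Title: Predicting Recombination Frequency from Additive Map Distance
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts recombination frequency between marker pairs on
    high-density linkage maps from their additive map distance. Implements a
    piecewise no-crossover probability function under a structural model of
    crossover interference (k crossovers placed uniformly in k equal-width
    map regions), marginalised over a multinomial distribution of bivalent
    crossover counts inferred from gametic crossover data by
    expectation-maximization, together with the classical inverse Haldane,
    Kosambi and capped linear mapping functions, a parametric bootstrap test
    of the obligate-crossover hypothesis, the intra-chromosomal component of
    genetic shuffling, an evaluation harness comparing predictors against
    empirical recombination frequencies, and a meiosis simulator that doubles
    as a Monte-Carlo oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, optparse
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
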