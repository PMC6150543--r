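Package: karyoMC
Title: Markov-Chain Models of Karyotype Evolution Under Chromosome
    Missegregation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and analyses the absorbing Markov chains that describe
    whole-chromosome copy-number evolution in clonally expanding tumor cell
    populations with numerical chromosomal instability. Provides the
    per-chromosome transition matrices (basic missegregation chain, its
    drift generator, the chromosome-score chain, and extensions for whole
    genome duplication and aneuploidy intolerance during early tumor
    growth), quasi-stationary (limiting) copy-number distributions via
    tridiagonal characteristic-polynomial recurrences and dense
    eigendecomposition, finite-generation dynamics with surviving
    fractions, population growth rates, the karyotype diversity index,
    and a direct stochastic lineage simulator used as an independent
    cross-check of every chain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), pracma, jsonlite, optparse, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'scores.R'
    'chains.R'
    'charpoly.R'
    'limiting.R'
    'dynamics.R'
    'karyotype.R'
    'simulate.R'
    'tables.R'
    'show-methods.R'
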