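Package: karyopop
Title: Chromosomal Inversion Polymorphism Analysis for Polytene Karyotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the cytogenetic analysis of chromosomal (inversion)
    polymorphism in natural populations scored on polytene chromosomes.
    Parses and validates banding-sequence maps written in the classical
    cytogenetic run notation, computes reversal distances and breakpoints
    between banding sequences of one chromosome arm, derives allele and
    genotype frequencies with polymorphism indices and Hardy-Weinberg
    goodness-of-fit tests, builds Nei (1972) standard genetic distance
    matrices and neighbor-joining trees between populations, classifies
    population cytogenetic structure types, and simulates genotype samples
    and derived banding sequences for validation. Ships the published
    banding-sequence pool and population tables of the midge Chironomus
    agilis as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
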