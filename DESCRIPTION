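Package: fluxmut
Title: Fluctuation-Assay Mutation Rates and Reporter-Gene Mutation Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of spontaneous mutation rates from Luria-Delbruck
    fluctuation assays (Drake per-culture median estimator with order-statistic
    confidence intervals, and Ma-Sandri-Sarkar maximum-likelihood estimation
    with Stewart-style confidence intervals), relative-rate computation against
    an isogenic wild type, classification of genetic interactions between
    mutator alleles (additive, multiplicative, synergistic, epistatic,
    suppressive), calling and classification of mutations in reporter-gene ORF
    sequences (base substitutions, 1-bp indels, clustered complex mutations,
    medium-size deletions between direct repeats, PCR-scored whole-gene
    deletions), decomposition of total rates into per-class rates, and a
    synthetic-data generator producing Luria-Delbruck-distributed colony
    counts and mutant reporter sequences with configurable spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
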