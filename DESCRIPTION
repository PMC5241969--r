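Package: regmutnet
Title: Disease Mutations on Multilayer Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Regmutnet", "Developers", email = "regmutnet@example.org",
           role = c("aut", "cre"))
Description: Maps disease-associated mutations onto a three-layer regulatory
    network (transcription-factor protein interfaces, TF binding motifs and
    chromatin-chromatin interactions) and computes the associated enrichment
    and disease-concordance statistics: odds-ratio enrichment of missense
    mutations on protein- and DNA-binding interfaces, length-normalised
    enrichment of non-coding mutations in chromatin-state segments and motif
    territory, classification of mutation pairs against a chromatin
    interaction network with cumulative-binomial concordance tests, SQRTVC
    normalised Hi-C contact comparisons, and a PWM log-likelihood motif
    scanner with degree-preserving network nulls. Includes seeded synthetic
    generators that emulate every input with planted, recoverable effect
    sizes, plus a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    yaml,
    Matrix,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
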