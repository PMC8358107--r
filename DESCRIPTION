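Package: insertlocus
Title: Localizing Transgene Insertions in Repetitive Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Locates a single-copy T-DNA insertion in a large, repetitive
    host genome by combining two independent evidence streams: chimeric
    (host-vector mixed) read detection against a combined host+vector
    reference, with junction extraction, clustering and interval calling;
    and bulked-segregant genetic mapping from an F2 population scored with
    codominant SSR markers (chi-square segregation test, strict
    cosegregation linkage rule, recombinant-bounded interval). A flank
    specificity scanner profiles how many near-identical genomic copies a
    junction flanking sequence has as it is extended in 0.5-kb steps, and
    an in-silico PCR module validates event-specific primer pairs.
    Includes a seeded simulator for repeat-bearing host genomes, clean
    construct insertions, short paired-end and error-prone long reads, and
    segregating F2 populations, so the whole pipeline is testable against
    a known truth insertion without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
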