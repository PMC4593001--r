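Package: miravoid
Title: Selection Against MicroRNA Target Sites in Maternal Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A microRNA target-site mutation model and population-genetic
    selection analyses for maternal transcripts. Defines canonical seed
    sixmer targets and their 18 one-nucleotide non-target neighbors, maps
    biallelic SNPs onto 3' UTRs to find target/non-target allele pairs,
    and computes target-allele frequency distributions, target avoidance
    and conservation statistics, a one-sided Kolmogorov-Smirnov left-shift
    test, derived-allele-frequency polarization against an outgroup with a
    singleton-excess test, and per-seed binomial enrichment of
    maternal-to-zygotic-transition destabilized transcripts with FDR
    control. Ships a synthetic population-data generator that draws
    target-allele frequencies from neutral or selected site-frequency
    spectra so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    vcfR,
    jsonlite,
    yaml,
    methods,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
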