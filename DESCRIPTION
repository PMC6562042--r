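Package: synmut
Title: Pan-Cancer Analysis of Somatic Synonymous Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curation, annotation, prioritization and cohort-level analysis of
    somatic synonymous (silent) mutations in cancer. Implements consequence
    re-classification from transcript sequence under nuclear and vertebrate
    mitochondrial genetic codes, per-sample deduplication, the six
    strand-symmetric substitution classes, mutational-signature-normalized
    recurrence, mutation-load statistics, coding-sequence and internal-exon
    positional depletion analyses, codon-usage-based expected amino-acid
    distributions, exonic splicing enhancer/silencer motif gain/loss scanning,
    quantile-rank analyses of ingested RNA-structure aberration scores, and a
    nine-parameter composite prioritization score with leave-one-out
    diagnostics. A synthetic-data generator produces toy transcriptomes and
    COSMIC-like mutation catalogs with injectable positional depletion,
    substitution-signature and recurrence structure so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
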