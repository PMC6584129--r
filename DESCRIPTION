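Package: silencescan
Title: Binding-Site Composition and Silencing Analysis for Nucleoid-Associated Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for xenogeneic-silencing studies of
    nucleoid-associated proteins (Lsr2, H-NS and relatives) in high-GC
    bacteria such as Streptomyces. Scores AT-richness of ChIP-derived
    binding sites against the chromosome baseline (sliding 20-nt AT-rich
    windows and 6-nt AT cores), associates binding sites with genes and
    specialized metabolic gene clusters, filters differential-expression
    tables and tests cluster enrichment with an exact binomial tail,
    designs GC-raised binding-site variants, and runs a rank-based
    differential pipeline for volatile-metabolome abundance matrices.
    Includes seeded synthetic-data generators (chromosome with planted
    AT-rich islands, clustered annotation, binding sites, expression and
    volatile tables) so every stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
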