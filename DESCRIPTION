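Package: chimeraScreen
Title: Detection of Chimeric Gene Models in Genome Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Audits genome annotations for chimeric gene models, i.e. single
    annotated genes that erroneously fuse two or more adjacent genes. A
    reference annotation is compared against an alternate annotation (for
    example one produced by a machine-learning gene predictor) using a
    trusted protein database: genes whose protein shows low median query
    coverage while the corresponding alternate models show high coverage,
    whose alternate hits are a subset of the reference hits, and whose hit
    coordinates form multiple distinct clusters along the protein are
    flagged as candidate chimeras. Companion analyses include reciprocal
    best-hit fusion/split classification by log2 length ratio, protein
    database coverage-signature screens, genome architecture metrics
    (N50, GC content, intergenic distances) with Spearman correlations,
    and a seeded simulator of genomes with planted chimeric fusions for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools,
    methods
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
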