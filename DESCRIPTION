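Package: antisenseq
Title: Strand-Specific Sense and Anti-Sense Transcriptome Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Splice-form-aware quantification of sense and anti-sense exonic
    transcription per gene from stranded paired-end RNA-seq alignments.
    Provides read-level depth normalization by seeded fragment subsampling,
    contamination-based sample quality control, coverage-based expression
    calls, biotype profiling, variability-based non-coding RNA selection,
    Jensen-Shannon-divergence hierarchical clustering, voom-style moderated-t
    differential expression with Benjamini-Hochberg q-values, and GREAT-style
    cis co-localization of non-coding genes to protein-coding neighbours.
    Includes a seeded simulator of stranded paired-end alignments with
    planted sense/anti-sense expression structure and contamination, used as
    the package's complete test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    methods,
    stats,
    utils,
    limma,
    yaml,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
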