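Package: senotf
Title: Senescence Expression Profiling and Promoter TFBS Enrichment Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable implementation of the computational analysis chain of a
    replicative-senescence transcriptomics study on serially passaged human
    diploid fibroblasts: differential-expression calling at explicit
    fold-change and FDR thresholds against a reference population-doubling
    (PD) level, exact-match scanning of degenerate IUPAC transcription-factor
    binding motifs over 1 kb promoter windows, occurrence-outlier target
    calling by the mean +/- SD rule, ranking of transcription factors by how
    many candidate targets their expression correlates with, and Fisher-exact
    enrichment of binding sites in promoters of differentially expressed genes
    versus all promoters.  Also provides the study's quantification utilities
    (population-doubling bookkeeping, multi-reference-gene qPCR normalization
    with error progression, ChIP-qPCR enrichment, band normalization, group
    t-tests) and a synthetic-data module that generates promoters with planted
    motif sites, expression matrices with planted differential expression, and
    qPCR Ct tables with known ground truth, so the full pipeline is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    BiocGenerics,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
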