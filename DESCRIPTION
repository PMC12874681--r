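Package: hetmethyl
Title: Heterozygosity-Corrected Whole-Genome Bisulfite Methylation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies cytosine methylation from whole-genome bisulfite
    sequencing in highly heterozygous genomes by masking C/T (and
    reverse-strand G/A) polymorphic cytosines identified from resequencing
    variant calls, then carries the corrected per-site levels through a full
    downstream analysis: genome-weighted per-context (CpG, CHG, CHH) levels,
    metagene profiles over gene and transposon bodies with 2 kb flanks,
    Fisher exact differential methylation calling at positions and in merged
    windows with Benjamini-Hochberg control, feature annotation of
    differentially methylated regions, region-by-context
    methylation-expression correlation, identification of DMR-mediated
    differentially expressed genes under five region-context pairing rules,
    and core versus period-specific DEG set classification. Includes a
    fully deterministic synthetic-data generator with a machine-readable
    truth table for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
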