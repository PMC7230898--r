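Package: vdrtargets
Title: Multi-Omic Identification and Characterization of Vitamin D Target
    Genes in Immune Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate vitamin D target genes by k-of-n consensus
    across differently filtered differential-expression datasets, characterizes
    the VDR-bound enhancer architecture of each gene (super-enhancer stitching
    from classified VDR ChIP-seq binding sites with H3K27ac continuity, or
    closest strong single enhancer), classifies ligand response time courses
    (primary/secondary targets, tertials, steepness groups), and integrates the
    epigenome, transcriptome and curation evidence into per-gene reports.
    Includes seeded synthetic-data generators with known ground truth and a
    deterministic fixture encoding published THP-1 reference profiles of
    15 key immune-related target genes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
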