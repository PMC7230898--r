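# vdrtargets

Identification and multi-omic characterization of vitamin D target
genes in immune cells.

The active vitamin D metabolite 1,25(OH)₂D₃ signals through the
vitamin D receptor (VDR), a transcription factor that binds genomic
enhancers and modulates hundreds of genes in monocytes and PBMCs. For
immunologists and regulatory genomicists who want to go from "lists of
differentially expressed genes" to "mechanistically annotated key
targets", `vdrtargets` implements a three-stage desk pipeline over
already-processed upstream data (DESeq2-style tables and classified
peak tracks):

1. **Consensus selection** — per-dataset filters (padj < α
   significance; the union of the top-100 genes by basal activity,
   fold change and lowest p-value; or an external membership list),
   followed by *k*-of-*n* consensus (default 4 of 5) and a full Venn
   partition.
2. **Enhancer profiling** — within ±1 Mb of each TSS, a
   **super-enhancer** is called when ≥ 3 classified VDR sites
   (P = persistent, T = transient, 24 = 24-h-only) lie within 20 kb
   with ≥ 1 strong P/T site and continuous H3K27ac across the span;
   otherwise the closest strong single P/T enhancer is selected. Calls
   carry a constellation label (classes ordered P < T < 24), the
   midpoint distance to the TSS, ligand-dependency of the enhancer and
   of the TSS window (any assay with differential p < 0.05), and an
   epigenome class 1–4 (super/single × dependent/not).
3. **Time-course classification** — a gene is a **primary** target if
   its expression rises significantly within 4 h of stimulation;
   tertials (top/mid/low) rank basal activity, inducibility (FC at
   24 h) and sensitivity (p at 24 h); steepness groups use the late
   log-ratio `s = log2(expr_24 / expr_4)` (group 3: s < 0.3, group 1:
   s ≥ 1.0, group 2 between).

Stage results are joined with a manual curation table into one report
row per gene. Seeded generators provide synthetic inputs with planted
ground truth for every stage, and `key_gene_fixture()` is a
deterministic bundle reproducing the published THP-1 reference
classification of the 15 key immune-related target genes.

## Worked example

```r
library(vdrtargets)

res <- run_fixture_pipeline()   # fixture -> enhancer calls -> time-course -> report
res$reports[1:6, c("gene_id", "constellation", "distance_kb", "super_enhancer",
                   "enhancer_ligand_dependent", "epigenome_class",
                   "transcriptome_group")]
#>  gene_id constellation distance_kb super_enhancer enhancer_ligand_dependent
#>   ACVRL1             P         0.0          FALSE                     FALSE
#>     CAMP             P         0.5          FALSE                      TRUE
#>     CD14        T-T-24        25.0           TRUE                      TRUE
#>     CD93       T-24-24        40.0           TRUE                     FALSE
#>    CEBPB             T         2.5          FALSE                     FALSE
#>      FN1             T       359.0          FALSE                      TRUE
#>  epigenome_class transcriptome_group
#>                4                   3
#>                3                   1
#>                1                   1
#>                2                   3
#>                4                   3
#>                3                   1
```

Reading the rows: *CD14* is driven by a ligand-dependent
super-enhancer (two strong transient VDR sites plus a 24-h-only site,
"T-T-24") 25 kb from its TSS — epigenome class 1 — and shows the
steepest expression response (group 1). *ACVRL1* binds VDR directly at
its TSS (distance 0) through a single persistent site whose region
does not respond to ligand (class 4), matching its flat late time
course (group 3). The full 15-row report reproduces the published
reference tables cell for cell; 13 of 15 genes are primary targets
(all but *FN1* and *CEBPB*).

Cross-tabulating responsiveness against enhancer dependency:

```r
cross_tab(res$reports, "transcriptome_group", "enhancer_ligand_dependent")
#>                    enhancer_ligand_dependent
#> transcriptome_group FALSE TRUE
#>                   1     0    4
#>                   2     4    2
#>                   3     4    1
```

All four highly responsive (group-1) genes carry ligand-inducible
enhancers. The one dependent group-3 gene is *NINJ1*, whose reference
record is internally inconsistent on this point (see the methods
vignette, `vignettes/vdrtargets-methods.Rmd`).

Synthetic studies with known truth:

```r
simulate_inputs("my_sim", n_datasets = 5, n_genes = 200, seed = 42)
# writes DE tables, peak BED, TSS TSV, time-course TSV and truth.json
```

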