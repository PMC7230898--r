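## Deterministic reference fixture: a synthetic-coordinate data bundle
## (one pseudo-chromosome per gene, TSS at 2 Mb) constructed so that the
## full pipeline reproduces the published epigenome and transcriptome
## classification of the 15 key immune-related vitamin D target genes in
## THP-1 cells. Coordinates are synthetic by design: the published record
## states enhancer distances and site constellations, not positions.

.FIXTURE_TSS <- 2000000L

## epigenome reference: distance (kb), VDR site constellation,
## super-enhancer flag, enhancer and TSS ligand-dependency, class;
## `side` places the enhancer down- (+1) or up- (-1) stream of the TSS.
.fixture_architecture <- function() {
  df <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
gene_id  distance_kb constellation super enh_dep tss_dep class side
CD14     25          T-T-24        yes   yes     yes     1     1
NINJ1    20          P-T-24        yes   yes     no      1     1
THEMIS2  19          P-24-24       yes   yes     no      1     1
CD93     40          T-24-24       yes   no      yes     2     1
SRGN     32          P-24-24       yes   no      no      2     1
THBD     80          T-24-24       yes   no      yes     2    -1
CAMP     0.5         P             no    yes     yes     3     1
FN1      359         T             no    yes     no      3     1
LILRB4   10          T             no    yes     no      3    -1
TREM1    0           T             no    yes     yes     3     1
ACVRL1   0           P             no    no      yes     4     1
CEBPB    2.5         T             no    no      no      4     1
LRRC25   4           T             no    no      yes     4    -1
MAPK13   3.5         P             no    no      no      4     1
SEMA6B   3           T             no    no      yes     4     1
")
  df$super <- df$super == "yes"
  df$enh_dep <- df$enh_dep == "yes"
  df$tss_dep <- df$tss_dep == "yes"
  df
}

## transcriptome reference: primary flag, tertials and steepness group,
## plus the trajectory (expr_0 / 2.5 / 4 / 24 h and p-values) realizing
## them: basal levels and 24 h fold changes ordered to yield the published
## tertials, late steepness log2(expr_24/expr_4) >= 1 for group 1,
## in [0.3, 1) for group 2 and < 0.3 for group 3, and early significance
## only for primary targets.
.fixture_dynamics <- function() {
  df <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
gene_id  primary t_basal t_fc t_p group expr_0 expr_2.5 expr_4  expr_24 p_2.5 p_4   p_24
CAMP     yes     low     top  low 1     100    140      200     800     0.04  0.01  4e-3
CD14     yes     low     top  top 1     90     120      157.5   630     0.01  0.005 1e-8
FN1      no      low     mid  mid 1     80     82       100     400     0.6   0.2   1e-4
TREM1    yes     low     top  top 1     70     90       113.75  455     0.02  0.01  2e-8
LILRB4   yes     top     low  mid 2     1000   1300     1768    2500    0.2   0.01  2e-4
LRRC25   yes     mid     top  top 2     500    1000     1980    3000    0.05  0.001 5e-8
MAPK13   yes     low     mid  low 2     60     100      166     270     0.1   0.005 3e-3
SEMA6B   yes     mid     top  mid 2     480    900      1742    2640    0.07  0.002 3e-4
THBD     yes     top     mid  top 2     950    1600     2687    3800    0.03  0.001 1e-7
THEMIS2  yes     mid     mid  mid 2     460    700      1062    1610    0.2   0.01  4e-4
ACVRL1   yes     mid     low  mid 3     440    600      903     968     0.1   0.01  5e-4
CD93     yes     top     low  low 3     900    1200     1679    1800    0.3   0.02  8e-3
CEBPB    no      top     low  low 3     850    1000     1350    1530    0.5   0.08  1e-2
NINJ1    yes     mid     mid  top 3     420    700      1136    1260    0.06  0.005 2e-7
SRGN     yes     top     low  low 3     800    1000     1236    1280    0.4   0.03  2e-2
")
  df$primary <- df$primary == "yes"
  df
}

.fixture_curation <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, na.strings = "NA",
             text = "
gene_id  verdict            functional_group              location
ACVRL1   keep               autoimmunity                  plasma_membrane
CAMP     keep               acute_response_to_infection   secreted
CD14     keep               acute_response_to_infection   plasma_membrane
CD93     keep               autoimmunity                  plasma_membrane
CEBPB    keep               autoimmunity                  nucleus
FN1      keep               acute_response_to_infection   secreted
LILRB4   keep               infection_in_general          plasma_membrane
LRRC25   keep               infection_in_general          plasma_membrane
MAPK13   keep               infection_in_general          cytoplasm
NINJ1    keep               autoimmunity                  plasma_membrane
SEMA6B   keep               infection_in_general          plasma_membrane
SRGN     keep               autoimmunity                  secreted
THBD     keep               infection_in_general          plasma_membrane
THEMIS2  keep               infection_in_general          nucleus
TREM1    keep               acute_response_to_infection   plasma_membrane
DENND6B  dismiss_unknown    NA                            NA
FBP1     dismiss_metabolic  NA                            NA
G0S2     dismiss_non_immune NA                            NA
")
}

## peak geometry of the fixture; all offsets relative to the TSS,
## 0-based half-open. Super-enhancers are three 200-bp VDR sites centered
## 8 kb apart with the span midpoint at the published distance; single
## enhancers are one 200-bp strong site at the published distance
## (overlapping the core promoter for distance 0). The H3K4me3 promoter
## peak carries the TSS-dependency flag and sits left of the TSS so it
## never overlaps a distance-0 enhancer placed right of it.
.fixture_peaks <- function(arch, anchors, cfg) {
  ns <- 0.5; sig <- 0.01
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r
  for (i in seq_len(nrow(arch))) {
    a <- arch[i, ]
    g <- a$gene_id
    chrom <- paste0("chr_", g)
    tss <- .FIXTURE_TSS
    add(.peak_row(chrom, tss - 180, tss - 20, paste0(g, "_k4_tss"), 12,
                  "H3K4me3", "ligand",
                  diff_pvalue = if (a$tss_dep) sig else ns))
    add(.peak_row(chrom, tss - 180, tss - 20, paste0(g, "_k4_tss_s"), 10,
                  "H3K4me3", "solvent"))
    add(.peak_row(chrom, tss - 250, tss + 250, paste0(g, "_acc_tss"), 8,
                  "accessibility", "ligand", diff_pvalue = ns))
    add(.peak_row(chrom, tss - 400, tss + 400, paste0(g, "_k27_tss"), 9,
                  "H3K27ac", "ligand", diff_pvalue = ns))
    cls <- strsplit(a$constellation, "-", fixed = TRUE)[[1L]]
    if (a$super) {
      d <- as.integer(a$distance_kb * 1000) * a$side
      centers <- d + c(-8000L, 0L, 8000L)
      strength <- ifelse(cls %in% c("P", "T"), "strong", "weak")
      dep_site <- which(strength == "strong")[1L]
      for (s in seq_along(cls))
        add(.peak_row(chrom, tss + centers[s] - 100, tss + centers[s] + 100,
                      sprintf("%s_vdr%d", g, s), 20, "VDR", "ligand",
                      site_class = cls[s], strength = strength[s],
                      diff_pvalue = if (a$enh_dep && s == dep_site)
                        sig else ns))
      add(.peak_row(chrom, tss + d - 8600, tss + d + 8600,
                    paste0(g, "_k27_enh"), 15, "H3K27ac", "ligand",
                    diff_pvalue = if (g == "CD14") sig else ns))
      add(.peak_row(chrom, tss + d - 8600, tss + d + 8600,
                    paste0(g, "_k27_enh_s"), 14, "H3K27ac", "solvent"))
    } else {
      if (a$distance_kb == 0) {
        s0 <- tss; e0 <- tss + 160
      } else {
        c0 <- tss + as.integer(a$distance_kb * 1000) * a$side
        s0 <- c0 - 100; e0 <- c0 + 100
      }
      add(.peak_row(chrom, s0, e0, paste0(g, "_vdr1"), 25, "VDR", "ligand",
                    site_class = cls, strength = "strong",
                    diff_pvalue = if (a$enh_dep) sig else ns))
      add(.peak_row(chrom, s0 - 400, e0 + 400, paste0(g, "_k27_enh"), 13,
                    "H3K27ac", "ligand", diff_pvalue = ns))
    }
  }
  as_peaks(do.call(rbind, rows))
}

#' Reference fixture of the 15 key immune-related target genes
#'
#' Builds a deterministic, download-free data bundle on a synthetic
#' coordinate system (one pseudo-chromosome per gene, TSS at 2 Mb) that
#' realizes the published THP-1 reference profiles of the 15 key
#' immune-related vitamin D target genes: super-/single-enhancer
#' architectures with their VDR site constellations, distances and
#' ligand-dependency flags, and response time courses yielding the
#' published primary-target flags, tertials and steepness groups. The
#' bundle contains no randomness and is byte-stable across runs.
#'
#' @return A list with elements `anchors`, `peaks`, `timecourse`,
#'   `curation`, `config`, and the reference classifications
#'   `expected_epigenome` and `expected_transcriptome`.
#' @examples
#' fx <- key_gene_fixture()
#' calls <- profile_genes(fx$anchors, fx$peaks, fx$config)
#' table(calls$kind)
#' @export
key_gene_fixture <- function() {
  cfg <- pipeline_config()
  arch <- .fixture_architecture()
  dyn <- .fixture_dynamics()
  anchors <- data.frame(
    gene_id = arch$gene_id,
    chrom = paste0("chr_", arch$gene_id),
    tss = .FIXTURE_TSS,
    strand = rep(c("+", "-"), length.out = nrow(arch)),
    stringsAsFactors = FALSE
  )
  tc <- dyn[c("gene_id", "expr_0", "expr_2.5", "expr_4", "expr_24",
              "p_2.5", "p_4", "p_24")]
  tc$fc24 <- tc$expr_24 / tc$expr_0
  list(
    anchors = anchors,
    peaks = .fixture_peaks(arch, anchors, cfg),
    timecourse = tc,
    curation = .fixture_curation(),
    config = cfg,
    expected_epigenome = arch[c("gene_id", "distance_kb", "constellation",
                                "super", "enh_dep", "tss_dep", "class")],
    expected_transcriptome = dyn[c("gene_id", "primary", "t_basal", "t_fc",
                                   "t_p", "group")]
  )
}

#' Run the full pipeline on the reference fixture
#'
#' Convenience wrapper: enhancer profiling, transcriptome classification
#' and report integration on [key_gene_fixture()].
#'
#' @return A list with elements `calls`, `transcriptome`, `reports` and
#'   `fixture`.
#' @export
run_fixture_pipeline <- function() {
  fx <- key_gene_fixture()
  calls <- profile_genes(fx$anchors, fx$peaks, fx$config)
  tx <- classify_transcriptome(fx$timecourse, fx$config)
  reports <- build_reports(calls, tx, fx$curation)
  list(calls = calls, transcriptome = tx, reports = reports, fixture = fx)
}

#' Write the reference fixture to disk
#'
#' Materializes [key_gene_fixture()] as plain-text files (peak BED, TSS
#' TSV, time-course TSV, curation TSV).
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
write_fixture <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- key_gene_fixture()
  paths <- list(
    peaks = file.path(dir, "peaks.bed"),
    tss = file.path(dir, "tss.tsv"),
    timecourse = file.path(dir, "timecourse.tsv"),
    curation = file.path(dir, "curation.tsv")
  )
  write_peaks(fx$peaks, paths$peaks)
  utils::write.table(fx$anchors, paths$tss, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fx$timecourse[setdiff(names(fx$timecourse), "fc24")],
                     paths$timecourse, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(fx$curation, paths$curation, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(paths)
}
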