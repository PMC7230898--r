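## Enhancer architecture around each TSS: window queries, VDR site strength,
## super-enhancer stitching (>= 3 classified VDR sites within 20 kb, one
## strong persistent/transient site, continuous H3K27ac), fallback to the
## closest strong single enhancer, ligand-dependency and the four-class
## epigenome categorization.

## midpoint in 0-based half-open coordinates
.mid0 <- function(gr) (GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2

## GRanges covering the 0-based half-open interval [start0, end0)
.gr0 <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = start0 + 1L, end = end0))
}

.tss_window_gr <- function(anchor, w) {
  .gr0(anchor$chrom, max(0L, anchor$tss - w), anchor$tss + w)
}

#' Peaks around a gene's TSS
#'
#' Returns every peak overlapping the 0-based half-open window
#' `[tss - radius, tss + radius)` on the anchor's chromosome.
#'
#' @param peaks A sorted peak `GRanges`.
#' @param anchor A one-row gene anchor (list or data.frame row with
#'   `gene_id`, `chrom`, `tss`, `strand`; `tss` 0-based).
#' @param radius Search radius in bp.
#' @return The overlapping peaks, sorted.
#' @export
query_window <- function(peaks, anchor, radius) {
  stopifnot(radius > 0)
  if (!(anchor$chrom %in% GenomeInfoDb::seqlevels(peaks))) {
    warning("chromosome '", anchor$chrom, "' absent from peak track",
            call. = FALSE)
    return(peaks[integer(0)])
  }
  win <- .gr0(anchor$chrom, max(0L, anchor$tss - radius), anchor$tss + radius)
  IRanges::subsetByOverlaps(peaks, win, ignore.strand = TRUE)
}

#' Label VDR peak strength
#'
#' Peaks with an explicit `strength` are kept as-is (strength classifications
#' inherited from upstream VDR cistrome analyses are authoritative);
#' unlabeled VDR peaks are called `strong` when their score reaches the
#' given quantile of VDR scores of the same condition.
#'
#' @param vdr_peaks A peak `GRanges` (VDR rows are labeled; others pass
#'   through untouched).
#' @param quantile Score quantile in (0, 1) above which a peak is strong.
#' @return The `GRanges` with `strength` filled in for VDR peaks.
#' @export
assign_strength <- function(vdr_peaks, quantile = 0.75) {
  stopifnot(quantile > 0, quantile < 1)
  if (length(vdr_peaks) == 0L) return(vdr_peaks)
  m <- S4Vectors::mcols(vdr_peaks)
  todo <- which(m$assay == "VDR" & is.na(m$strength))
  for (cond in unique(m$condition[todo])) {
    idx <- todo[m$condition[todo] == cond]
    ref <- m$score[m$assay == "VDR" & m$condition == cond]
    thr <- stats::quantile(ref, probs = quantile, names = FALSE, type = 7)
    m$strength[idx] <- ifelse(m$score[idx] >= thr, "strong", "weak")
  }
  S4Vectors::mcols(vdr_peaks) <- m
  vdr_peaks
}

#' H3K27ac continuity over a span
#'
#' TRUE when the union of H3K27ac intervals, after merging intervals
#' separated by at most `max_gap` bp, contains a single interval covering
#' the whole span ("a continuous active-chromatin mark throughout the
#' enhancer").
#'
#' @param span A length-1 `GRanges` (the candidate enhancer span).
#' @param h3k27ac A peak `GRanges` of H3K27ac intervals.
#' @param max_gap Maximal bridged gap in bp.
#' @return Logical.
#' @export
h3k27ac_continuity <- function(span, h3k27ac, max_gap = 1000L) {
  if (length(h3k27ac) == 0L) return(FALSE)
  same <- h3k27ac[as.character(GenomicRanges::seqnames(h3k27ac)) ==
                  as.character(GenomicRanges::seqnames(span))[1L]]
  if (length(same) == 0L) return(FALSE)
  merged <- IRanges::reduce(GenomicRanges::ranges(same),
                            min.gapwidth = max_gap + 1L)
  any(IRanges::start(merged) <= GenomicRanges::start(span)[1L] &
      IRanges::end(merged) >= GenomicRanges::end(span)[1L])
}

#' Call a super-enhancer near one gene
#'
#' Scans all start-contiguous groups of at least `se_min_sites` VDR sites
#' whose first-start-to-last-end extent is at most `se_window_bp`. A group
#' qualifies when it contains at least one strong persistent or transient
#' site and H3K27ac is continuous across its span. Among qualifying
#' clusters the one whose span midpoint lies nearest the TSS is returned
#' (ties: more member sites, then leftmost span).
#'
#' @param vdr_in_window VDR peaks of the gene's window (one condition,
#'   strengths assigned).
#' @param h3k27ac H3K27ac peaks of the window.
#' @param anchor The gene anchor (see [query_window()]).
#' @param cfg A [pipeline_config()].
#' @return A list of class `stitched_cluster` with elements `sites`, `span`,
#'   `has_strong_PT`, `h3k27ac_continuous`, or `NULL` when no group
#'   qualifies.
#' @export
call_super_enhancer <- function(vdr_in_window, h3k27ac, anchor, cfg) {
  n <- length(vdr_in_window)
  if (n < cfg$se_min_sites) return(NULL)
  gr <- sort_peaks(vdr_in_window)
  m <- S4Vectors::mcols(gr)
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  strong_pt <- m$assay == "VDR" & !is.na(m$strength) &
    m$strength == "strong" & m$site_class %in% c("P", "T")
  best <- NULL
  for (i in seq_len(n - cfg$se_min_sites + 1L)) {
    maxend <- end0[i]
    for (j in i:n) {
      maxend <- max(maxend, end0[j])
      if (maxend - start0[i] > cfg$se_window_bp) break
      if (j - i + 1L < cfg$se_min_sites) next
      if (!any(strong_pt[i:j])) next
      span <- .gr0(anchor$chrom, start0[i], maxend)
      if (!h3k27ac_continuity(span, h3k27ac, cfg$h3k27ac_max_gap_bp)) next
      cand <- list(i = i, j = j,
                   dist = abs((start0[i] + maxend) / 2 - anchor$tss),
                   size = j - i + 1L, start = start0[i], end = maxend)
      if (is.null(best) ||
          cand$dist < best$dist ||
          (cand$dist == best$dist && cand$size > best$size) ||
          (cand$dist == best$dist && cand$size == best$size &&
           cand$start < best$start))
        best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  sites <- gr[best$i:best$j]
  structure(list(
    sites = sites,
    span = .gr0(anchor$chrom, best$start, best$end),
    has_strong_PT = TRUE,
    h3k27ac_continuous = TRUE
  ), class = "stitched_cluster")
}

#' Closest strong single enhancer
#'
#' Fallback when no super-enhancer qualifies: among strong VDR sites of
#' class persistent or transient, the one whose midpoint lies closest to
#' the TSS (ties broken toward the upstream, i.e. coordinate-left, site,
#' then by start).
#'
#' @param vdr_in_window VDR peaks of the window (strengths assigned).
#' @param anchor The gene anchor.
#' @return A length-1 peak `GRanges`, or `NULL` when no strong
#'   persistent/transient site exists.
#' @export
select_single_enhancer <- function(vdr_in_window, anchor) {
  m <- S4Vectors::mcols(vdr_in_window)
  ok <- m$assay == "VDR" & !is.na(m$strength) & m$strength == "strong" &
    m$site_class %in% c("P", "T")
  cand <- vdr_in_window[ok]
  if (length(cand) == 0L) return(NULL)
  mid <- .mid0(cand)
  d <- abs(mid - anchor$tss)
  ord <- order(d, mid >= anchor$tss, GenomicRanges::start(cand))
  cand[ord[1L]]
}

#' Enhancer constellation label
#'
#' Joins the VDR site classes of an enhancer with "-", ordered by class
#' precedence persistent < transient < 24-h-only (e.g. "T-T-24");
#' independent of input order.
#'
#' @param sites A VDR peak `GRanges` with `site_class` set on every site.
#' @return A string.
#' @export
constellation_label <- function(sites) {
  cls <- S4Vectors::mcols(sites)$site_class
  if (length(cls) == 0L) stop("no sites given", call. = FALSE)
  if (anyNA(cls))
    stop("all sites of a constellation need a site_class", call. = FALSE)
  paste(cls[order(match(cls, c("P", "T", "24")))], collapse = "-")
}

#' Ligand dependency of a genomic region
#'
#' TRUE when at least one ligand-condition peak of any assay overlapping
#' the region responds significantly (differential p-value below `alpha`)
#' to ligand treatment. Peaks without a differential p-value count as
#' non-significant.
#'
#' @param region A length-1 `GRanges`.
#' @param peaks A peak `GRanges` (any assays/conditions).
#' @param alpha Significance level.
#' @return Logical.
#' @export
region_ligand_dependency <- function(region, peaks, alpha = 0.05) {
  if (length(peaks) == 0L) return(FALSE)
  hits <- IRanges::subsetByOverlaps(peaks, region, ignore.strand = TRUE)
  m <- S4Vectors::mcols(hits)
  any(m$condition == "ligand" & !is.na(m$diff_pvalue) &
      m$diff_pvalue < alpha)
}

#' Enhancer-TSS distance in kb
#'
#' 0.0 when the region overlaps the core-promoter window
#' `[tss - tss_window, tss + tss_window)` (direct TSS binding); otherwise
#' the unsigned distance from the region midpoint to the TSS, in kb rounded
#' to one decimal.
#'
#' @param region A length-1 `GRanges` on the anchor's chromosome.
#' @param anchor The gene anchor.
#' @param tss_window Core-promoter half-width in bp.
#' @return A number (kb, one decimal).
#' @export
distance_to_tss <- function(region, anchor, tss_window = 200L) {
  if (as.character(GenomicRanges::seqnames(region))[1L] != anchor$chrom)
    stop("region and anchor are on different chromosomes", call. = FALSE)
  win <- .tss_window_gr(anchor, tss_window)
  if (IRanges::overlapsAny(region, win, ignore.strand = TRUE)[1L])
    return(0.0)
  round(abs(.mid0(region) - anchor$tss) / 1000, 1)
}

#' Four-class epigenome category
#'
#' Class 1: super-enhancer, ligand-dependent; class 2: super-enhancer, not
#' dependent; class 3: single enhancer, dependent; class 4: single
#' enhancer, not dependent.
#'
#' @param kind `"super"`, `"single"` or `"none"`.
#' @param ligand_dependent Logical ligand dependency of the enhancer.
#' @return Integer class, or `NA` (with a warning) when `kind` is "none".
#' @export
classify_epigenome <- function(kind, ligand_dependent) {
  if (kind == "none") {
    warning("no enhancer call; epigenome class undefined", call. = FALSE)
    return(NA_integer_)
  }
  if (kind == "super") {
    if (ligand_dependent) 1L else 2L
  } else {
    if (ligand_dependent) 3L else 4L
  }
}

.empty_call <- function(gene_id) {
  data.frame(
    gene_id = gene_id, kind = "none", n_sites = 0L,
    constellation = NA_character_, region_chrom = NA_character_,
    region_start = NA_integer_, region_end = NA_integer_,
    distance_kb = NA_real_, enhancer_ligand_dependent = NA,
    tss_ligand_dependent = NA, epigenome_class = NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Profile the enhancer architecture of one gene
#'
#' Composes the full per-gene procedure: window query (+/- 1 Mb by
#' default), VDR strength assignment, super-enhancer stitching with
#' fallback to the closest strong single enhancer, constellation label,
#' ligand dependency of the enhancer region and of the TSS window,
#' enhancer-TSS distance and the four-class epigenome category. VDR sites
#' are taken from the ligand-condition classified track; ligand dependency
#' considers all four assays.
#'
#' @param anchor A one-row gene anchor.
#' @param peaks The full sorted peak `GRanges` (all assays).
#' @param cfg A [pipeline_config()].
#' @return A one-row data.frame (enhancer call); `kind` is "none" when no
#'   qualifying enhancer exists, with `tss_ligand_dependent` still
#'   evaluated.
#' @export
profile_gene <- function(anchor, peaks, cfg = pipeline_config()) {
  win <- suppressWarnings(query_window(peaks, anchor, cfg$search_radius_bp))
  out <- .empty_call(anchor$gene_id)
  tssw <- .tss_window_gr(anchor, cfg$tss_window_bp)
  out$tss_ligand_dependent <- region_ligand_dependency(tssw, win, cfg$alpha)
  m <- S4Vectors::mcols(win)
  vdr <- win[m$assay == "VDR" & m$condition == "ligand"]
  if (length(vdr) == 0L) return(out)
  vdr <- assign_strength(vdr, cfg$strength_quantile)
  k27 <- win[m$assay == "H3K27ac"]
  se <- call_super_enhancer(vdr, k27, anchor, cfg)
  if (!is.null(se)) {
    sites <- se$sites
    region <- se$span
    out$kind <- "super"
  } else {
    single <- select_single_enhancer(vdr, anchor)
    if (is.null(single)) return(out)
    sites <- single
    region <- GenomicRanges::granges(single)
    out$kind <- "single"
  }
  out$n_sites <- length(sites)
  out$constellation <- constellation_label(sites)
  out$region_chrom <- anchor$chrom
  out$region_start <- GenomicRanges::start(region) - 1L
  out$region_end <- GenomicRanges::end(region)
  out$distance_kb <- distance_to_tss(region, anchor, cfg$tss_window_bp)
  out$enhancer_ligand_dependent <-
    region_ligand_dependency(region, win, cfg$alpha)
  out$epigenome_class <-
    classify_epigenome(out$kind, out$enhancer_ligand_dependent)
  out
}

#' Profile many genes
#'
#' @param anchors A gene-anchor data.frame (see [read_tss()]).
#' @param peaks The full sorted peak `GRanges`.
#' @param cfg A [pipeline_config()].
#' @return A data.frame of enhancer calls, one row per anchor, in anchor
#'   order.
#' @export
profile_genes <- function(anchors, peaks, cfg = pipeline_config()) {
  calls <- lapply(seq_len(nrow(anchors)), function(i)
    profile_gene(anchors[i, ], peaks, cfg))
  do.call(rbind, calls)
}

#' Export called enhancer regions as BED
#'
#' @param calls An enhancer-call data.frame from [profile_genes()].
#' @param path Output BED path (0-based half-open).
#' @return Invisibly, `path`.
#' @export
write_enhancer_bed <- function(calls, path) {
  keep <- calls$kind != "none"
  df <- data.frame(
    chrom = calls$region_chrom[keep],
    start = calls$region_start[keep],
    end = calls$region_end[keep],
    name = paste0(calls$gene_id[keep], "_", calls$kind[keep]),
    score = 0L,
    strand = "."
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
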