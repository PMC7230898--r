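## Joins consensus, epigenome and transcriptome results with the manual
## curation table into per-gene reports and cross-tabulations.

#' Apply a curation table to a gene set
#'
#' Keeps genes with verdict `keep`. Genes without a curation record are
#' kept (verdict `NA`) with a warning, so an incomplete curation never
#' silently drops candidates; explicit dismissals (`dismiss_metabolic`,
#' `dismiss_non_immune`, `dismiss_unknown`) remove genes.
#'
#' @param genes A character vector of gene ids.
#' @param curation A curation data.frame (see [read_curation()]).
#' @return The kept gene ids (sorted).
#' @export
apply_curation <- function(genes, curation) {
  genes <- unique(genes)
  verdict <- stats::setNames(curation$verdict, curation$gene_id)
  uncovered <- setdiff(genes, curation$gene_id)
  if (length(uncovered))
    warning(length(uncovered), " gene(s) lack a curation record and are ",
            "kept with verdict NA: ", paste(uncovered, collapse = ", "),
            call. = FALSE)
  kept <- genes[is.na(verdict[genes]) | verdict[genes] == "keep"]
  sort(kept)
}

#' Build integrated per-gene reports
#'
#' Inner-joins the enhancer calls and transcriptome classes over the
#' curated gene set and attaches consensus support and curation fields.
#' Stages missing a gene contribute `NA` fields with a warning; a duplicate
#' gene in any stage is an error.
#'
#' @param enhancer_calls Enhancer-call data.frame from [profile_genes()].
#' @param transcriptome Classification data.frame from
#'   [classify_transcriptome()].
#' @param curation Curation data.frame (see [read_curation()]).
#' @param consensus Optional result of [consensus_targets()]; supplies the
#'   per-gene support counts.
#' @param genes Optional explicit gene set; defaults to the union of the
#'   staged genes, curated via [apply_curation()].
#' @return A report data.frame, one row per kept gene, sorted by gene id.
#' @export
build_reports <- function(enhancer_calls, transcriptome, curation,
                          consensus = NULL, genes = NULL) {
  for (nm in c("enhancer_calls", "transcriptome")) {
    df <- get(nm)
    if (anyDuplicated(df$gene_id))
      stop("duplicated gene_id in ", nm, call. = FALSE)
  }
  if (is.null(genes))
    genes <- union(enhancer_calls$gene_id, transcriptome$gene_id)
  if (length(genes) == 0L) {
    empty <- as.data.frame(stats::setNames(
      replicate(length(.report_columns), character(0), simplify = FALSE),
      .report_columns))
    return(empty)
  }
  kept <- apply_curation(genes, curation)
  miss_e <- setdiff(kept, enhancer_calls$gene_id)
  miss_t <- setdiff(kept, transcriptome$gene_id)
  if (length(miss_e))
    warning("no enhancer call for: ", paste(miss_e, collapse = ", "),
            call. = FALSE)
  if (length(miss_t))
    warning("no transcriptome class for: ", paste(miss_t, collapse = ", "),
            call. = FALSE)
  e <- enhancer_calls[match(kept, enhancer_calls$gene_id), ]
  t <- transcriptome[match(kept, transcriptome$gene_id), ]
  cu <- curation[match(kept, curation$gene_id), ]
  support <- if (!is.null(consensus))
    unname(consensus$support[kept]) else NA_integer_
  data.frame(
    gene_id = kept,
    consensus_support = as.integer(support),
    kind = e$kind,
    constellation = e$constellation,
    distance_kb = e$distance_kb,
    super_enhancer = ifelse(is.na(e$kind), NA, e$kind == "super"),
    enhancer_ligand_dependent = e$enhancer_ligand_dependent,
    tss_ligand_dependent = e$tss_ligand_dependent,
    epigenome_class = e$epigenome_class,
    primary_target = t$primary_target,
    tertial_basal = t$tertial_basal,
    tertial_fc = t$tertial_fc,
    tertial_p = t$tertial_p,
    transcriptome_group = t$transcriptome_group,
    verdict = ifelse(is.na(cu$verdict), NA_character_, cu$verdict),
    functional_group = cu$functional_group,
    location = cu$location,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Cross-tabulate two report fields
#'
#' Contingency counts over report rows; rows with `NA` in either field are
#' dropped, so counts sum to the number of genes with both labels defined.
#'
#' @param reports A report data.frame from [build_reports()].
#' @param row_field,col_field Report column names.
#' @return A `table`.
#' @export
cross_tab <- function(reports, row_field, col_field) {
  for (f in c(row_field, col_field))
    if (!f %in% names(reports))
      stop("unknown report field: ", f, call. = FALSE)
  table(reports[[row_field]], reports[[col_field]],
        dnn = c(row_field, col_field), useNA = "no")
}
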