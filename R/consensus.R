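## Consensus gene selection across differently filtered
## differential-expression datasets: per-dataset filters, k-of-n membership,
## and the Venn partition used for reporting.

#' Significant genes of one dataset
#'
#' The "unfiltered" strategy: every gene whose adjusted p-value is below
#' `alpha` is a target gene of that dataset.
#'
#' @param records A differential-expression data.frame from
#'   [read_de_table()] (one dataset).
#' @param alpha Significance level on `padj`.
#' @return A character vector of gene ids (sorted, unique).
#' @export
filter_unfiltered_significant <- function(records, alpha = 0.05) {
  if (nrow(records) == 0L) return(character(0))
  sort(unique(records$gene_id[!is.na(records$padj) & records$padj < alpha]))
}

#' Top-N union filter of one dataset
#'
#' Takes the union of three criterion-wise top-N lists: highest basal
#' activity, highest inducibility (log2 fold change) and lowest p-value.
#' The result therefore has between N and 3N genes. Ties at rank N are
#' broken by gene id (lexicographic), making the filter deterministic and
#' order-independent.
#'
#' @param records A differential-expression data.frame (one dataset).
#' @param n Number of genes per ranking criterion.
#' @return A character vector of gene ids (sorted, unique).
#' @export
filter_top_n_union <- function(records, n = 100L) {
  stopifnot(n >= 1L)
  if (nrow(records) == 0L) return(character(0))
  top <- function(value, decreasing) {
    ord <- order(value, records$gene_id, decreasing = c(decreasing, FALSE),
                 method = "radix", na.last = TRUE)
    records$gene_id[ord][seq_len(min(n, nrow(records)))]
  }
  sort(unique(c(top(records$basal, TRUE),
                top(records$log2fc, TRUE),
                top(records$pvalue, FALSE))))
}

#' k-of-n consensus of gene sets
#'
#' Genes present in at least `k` of the input sets. `k = 1` is the union,
#' `k = length(sets)` the intersection.
#'
#' @param sets A list of character vectors of gene ids.
#' @param k Minimum number of sets a gene must belong to.
#' @return A character vector of gene ids (sorted).
#' @export
k_of_n_consensus <- function(sets, k) {
  if (length(sets) == 0L) stop("'sets' must not be empty", call. = FALSE)
  if (k < 1L || k > length(sets))
    stop("'k' must lie between 1 and the number of sets", call. = FALSE)
  counts <- table(unlist(lapply(sets, unique), use.names = FALSE))
  sort(names(counts)[counts >= k])
}

#' Venn partition of gene sets
#'
#' Assigns every gene of the union to exactly one subset signature (a
#' bit string over the input sets, e.g. "101" = present in sets 1 and 3
#' of 3). Region sizes therefore sum to the size of the union.
#'
#' @param sets A list (at most 8) of character vectors of gene ids;
#'   names, if present, are kept as dataset labels.
#' @return An object of class `venn_partition`: a list with elements
#'   `regions` (named list signature -> gene ids), `counts` (named integer
#'   vector) and `labels` (dataset labels).
#' @export
venn_partition <- function(sets) {
  if (length(sets) == 0L) stop("'sets' must not be empty", call. = FALSE)
  if (length(sets) > 8L)
    stop("at most 8 sets are supported", call. = FALSE)
  sets <- lapply(sets, unique)
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  sig <- apply(member, 1L, function(row) paste(as.integer(row), collapse = ""))
  regions <- split(universe, sig)
  structure(list(
    regions = regions,
    counts = vapply(regions, length, integer(1)),
    labels = if (is.null(names(sets)))
      paste0("set", seq_along(sets)) else names(sets)
  ), class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition over", length(x$labels), "sets (",
      paste(x$labels, collapse = ", "), ")\n")
  for (sig in names(x$counts))
    cat(sprintf("  %s  %d gene(s)\n", sig, x$counts[[sig]]))
  invisible(x)
}

#' Apply a per-dataset filter strategy
#'
#' @param records A differential-expression data.frame (one dataset).
#' @param strategy A list with element `name` (one of
#'   `"unfiltered_significant"`, `"top_n_union"`, `"external_list"`) and the
#'   matching parameter (`alpha`, `top_n`, or `list_path`/`genes`).
#'   External lists (e.g. SOM-derived memberships from upstream tools) are
#'   taken as given, one gene id per line.
#' @param cfg A [pipeline_config()] supplying defaults.
#' @return A character vector of gene ids.
#' @export
apply_filter_strategy <- function(records, strategy, cfg = pipeline_config()) {
  switch(strategy$name,
    unfiltered_significant = filter_unfiltered_significant(
      records, alpha = strategy$alpha %||% cfg$alpha),
    top_n_union = filter_top_n_union(
      records, n = strategy$top_n %||% cfg$top_n),
    external_list = {
      genes <- strategy$genes %||% readLines(strategy$list_path)
      sort(unique(genes[nzchar(genes)]))
    },
    stop("unknown filter strategy: ", strategy$name, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Consensus target genes across datasets
#'
#' Applies one filter strategy per dataset and returns the genes shared by
#' at least `k` of the filtered sets, together with the full Venn partition
#' and the all-datasets core set.
#'
#' @param tables A named list of differential-expression data.frames, one
#'   per dataset.
#' @param strategies A list of filter strategies, parallel to `tables`
#'   (recycled if of length 1).
#' @param k Consensus threshold; defaults to `cfg$consensus_k`.
#' @param cfg A [pipeline_config()].
#' @return A list with elements `consensus` (gene ids in >= k sets),
#'   `core` (gene ids in all sets), `support` (named integer vector of
#'   per-gene set counts), `sets` (the filtered per-dataset sets) and
#'   `partition` (a [venn_partition()]).
#' @export
consensus_targets <- function(tables, strategies, k = NULL,
                              cfg = pipeline_config()) {
  if (is.null(k)) k <- cfg$consensus_k
  if (length(strategies) == 1L && length(tables) > 1L)
    strategies <- rep(strategies, length(tables))
  if (length(strategies) != length(tables))
    stop("need one filter strategy per dataset", call. = FALSE)
  sets <- mapply(apply_filter_strategy, tables, strategies,
                 MoreArgs = list(cfg = cfg), SIMPLIFY = FALSE)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("dataset", seq_along(sets))
  counts <- table(unlist(lapply(sets, unique), use.names = FALSE))
  support <- stats::setNames(as.integer(counts), names(counts))
  list(
    consensus = k_of_n_consensus(sets, k),
    core = k_of_n_consensus(sets, length(sets)),
    support = support,
    sets = sets,
    partition = venn_partition(sets)
  )
}
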