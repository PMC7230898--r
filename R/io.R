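## Readers and writers for the tabular/BED interfaces shared by all stages.
## External coordinates are BED-style 0-based half-open; peaks live in
## GRanges (1-based closed) internally and are converted at these boundaries.

.ASSAYS <- c("VDR", "H3K27ac", "H3K4me3", "accessibility")
.CONDITIONS <- c("ligand", "solvent")
.SITE_CLASSES <- c("P", "T", "24")

.default_de_map <- c(gene_id = "gene_id", basal = "baseMean",
                     log2fc = "log2FoldChange", pvalue = "pvalue",
                     padj = "padj")

.na_dot <- function(x) {
  x <- as.character(x)
  x[x %in% c(".", "NA", "")] <- NA_character_
  x
}

#' Read a differential-expression table
#'
#' Parses one dataset's differential-expression statistics (one row per gene)
#' from a TSV. Default column names follow DESeq2 result headers; a custom
#' mapping can be supplied for other upstream tools.
#'
#' @param path Path to a tab-separated file with a header line.
#' @param dataset_id Identifier attached to every record of this table.
#' @param col_map Named character vector mapping the internal field names
#'   `gene_id`, `basal`, `log2fc`, `pvalue`, `padj` to the file's column
#'   headers.
#' @return A data.frame with columns `gene_id`, `dataset_id`, `basal`,
#'   `log2fc`, `pvalue`, `padj`, in file order.
#' @export
read_de_table <- function(path, dataset_id,
                          col_map = .default_de_map) {
  stopifnot(is.character(dataset_id), length(dataset_id) == 1L)
  map <- .default_de_map
  map[names(col_map)] <- col_map
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unname(map), names(raw))
  if (length(missing))
    stop("differential-expression table '", path,
         "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- data.frame(
    gene_id = .na_dot(raw[[map[["gene_id"]]]]),
    dataset_id = dataset_id,
    basal = raw[[map[["basal"]]]],
    log2fc = raw[[map[["log2fc"]]]],
    pvalue = raw[[map[["pvalue"]]]],
    padj = raw[[map[["padj"]]]],
    stringsAsFactors = FALSE
  )
  for (col in c("basal", "pvalue", "padj", "log2fc")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(v))
    if (length(bad))
      stop("non-numeric value in column '", map[[col]], "' at data line ",
           bad[1L], " of '", path, "'", call. = FALSE)
    df[[col]] <- v
  }
  if (anyNA(df$gene_id))
    stop("missing gene identifier at data line ",
         which(is.na(df$gene_id))[1L], " of '", path, "'", call. = FALSE)
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup))
    stop("duplicated gene(s) within dataset '", dataset_id, "': ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  if (any(df$basal < 0, na.rm = TRUE))
    stop("negative basal expression in '", path, "'", call. = FALSE)
  rownames(df) <- NULL
  df
}

#' Build a peak GRanges from BED-style fields
#'
#' Validates assay/condition/site-class fields and converts 0-based half-open
#' intervals into a sorted `GRanges` with metadata columns `name`, `score`,
#' `assay`, `condition`, `site_class`, `strength` and `diff_pvalue`.
#' VDR site classes are "P" (persistent), "T" (transient) and "24"
#' (24 h only); `site_class`/`strength` must be `NA` for non-VDR assays.
#'
#' @param df A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `name`, `score`, `strand`, `assay`, `condition`,
#'   `site_class`, `strength`, `diff_pvalue`.
#' @return A sorted `GRanges`.
#' @export
as_peaks <- function(df) {
  req <- c("chrom", "start", "end", "name", "score", "strand", "assay",
           "condition", "site_class", "strength", "diff_pvalue")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("peak table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$site_class <- .na_dot(df$site_class)
  df$strength <- .na_dot(df$strength)
  df$diff_pvalue <- suppressWarnings(as.numeric(.na_dot(df$diff_pvalue)))
  n <- nrow(df)
  if (n == 0L) return(.empty_peaks())
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("peak record ", bad[1L], ": start must be < end", call. = FALSE)
  if (!all(df$assay %in% .ASSAYS))
    stop("unknown assay value(s): ",
         paste(setdiff(unique(df$assay), .ASSAYS), collapse = ", "),
         call. = FALSE)
  if (!all(df$condition %in% .CONDITIONS))
    stop("unknown condition value(s): ",
         paste(setdiff(unique(df$condition), .CONDITIONS), collapse = ", "),
         call. = FALSE)
  bad_class <- which(!is.na(df$site_class) & df$assay != "VDR")
  if (length(bad_class))
    stop("peak record ", bad_class[1L],
         ": site_class is only defined for VDR peaks", call. = FALSE)
  if (!all(df$site_class %in% c(.SITE_CLASSES, NA)))
    stop("unknown site_class value(s)", call. = FALSE)
  if (!all(df$strength %in% c("strong", "weak", NA)))
    stop("unknown strength value(s)", call. = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = as.character(df$name),
    score = as.numeric(df$score),
    assay = df$assay,
    condition = df$condition,
    site_class = df$site_class,
    strength = df$strength,
    diff_pvalue = df$diff_pvalue
  )
  sort_peaks(gr)
}

.empty_peaks <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = character(0), score = numeric(0), assay = character(0),
    condition = character(0), site_class = character(0),
    strength = character(0), diff_pvalue = numeric(0)
  )
  gr
}

#' Sort peaks by (chromosome, start, end)
#'
#' Deterministic, strand-ignorant ordering used throughout; chromosome names
#' are ordered lexicographically so the result does not depend on input order.
#'
#' @param gr A peak `GRanges`.
#' @return The sorted `GRanges`.
#' @export
sort_peaks <- function(gr) {
  if (length(gr) == 0L) return(gr)
  GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
  ord <- order(as.integer(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr), GenomicRanges::end(gr),
               S4Vectors::mcols(gr)$name)
  gr[ord]
}

#' Read a peak track (BED6+5)
#'
#' Columns 1-6 are standard BED (0-based half-open); columns 7-11 carry
#' `assay`, `condition`, `site_class`, `strength` and `diff_pvalue`, with
#' "." or "NA" denoting missing values.
#'
#' @param path Path to the BED-derived file (no header).
#' @return A sorted peak `GRanges` (see [as_peaks()]).
#' @export
read_peaks <- function(path) {
  raw <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE,
                      colClasses = c("character", "integer", "integer",
                                     "character", "numeric", "character",
                                     "character", "character", "character",
                                     "character", "character")),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(NULL)
      stop(e)
    })
  if (is.null(raw)) return(.empty_peaks())
  if (ncol(raw) != 11L)
    stop("peak file '", path, "' must have 11 tab-separated columns ",
         "(BED6 + assay, condition, site_class, strength, diff_pvalue)",
         call. = FALSE)
  names(raw) <- c("chrom", "start", "end", "name", "score", "strand",
                  "assay", "condition", "site_class", "strength",
                  "diff_pvalue")
  as_peaks(raw)
}

#' Write a peak track (BED6+5)
#'
#' Inverse of [read_peaks()]; intervals are emitted 0-based half-open.
#'
#' @param gr A peak `GRanges`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_peaks <- function(gr, path) {
  m <- S4Vectors::mcols(gr)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = m$name,
    score = m$score,
    strand = as.character(GenomicRanges::strand(gr)),
    assay = m$assay,
    condition = m$condition,
    site_class = ifelse(is.na(m$site_class), ".", m$site_class),
    strength = ifelse(is.na(m$strength), ".", m$strength),
    diff_pvalue = ifelse(is.na(m$diff_pvalue), ".",
                         format(m$diff_pvalue, trim = TRUE)),
    stringsAsFactors = FALSE
  )
  df$strand[df$strand == "*"] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' Expects a TSV with header columns `gene_id`, `chrom`, `tss`, `strand`,
#' where `tss` is a 0-based position.
#'
#' @param path Path to the annotation TSV.
#' @return A data.frame of gene anchors, one row per gene.
#' @export
read_tss <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing <- setdiff(c("gene_id", "chrom", "tss", "strand"), names(df))
  if (length(missing))
    stop("TSS table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- df[c("gene_id", "chrom", "tss", "strand")]
  if (anyDuplicated(df$gene_id))
    stop("duplicated gene_id in TSS table", call. = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop("TSS strand must be '+' or '-'", call. = FALSE)
  if (any(df$tss < 0))
    stop("TSS positions must be non-negative", call. = FALSE)
  df$tss <- as.integer(df$tss)
  df
}

#' Read a time-course expression table
#'
#' Expects columns `gene_id`, `expr_0`, `expr_2.5`, `expr_4`, `expr_24`,
#' `p_2.5`, `p_4`, `p_24` (p-values of each time point against basal).
#'
#' @param path Path to the TSV.
#' @return A data.frame, one row per gene, with an `fc24` column
#'   (24 h / basal expression) appended.
#' @export
read_timecourse <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("gene_id", "expr_0", "expr_2.5", "expr_4", "expr_24",
           "p_2.5", "p_4", "p_24")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("time-course table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- df[req]
  if (anyDuplicated(df$gene_id))
    stop("duplicated gene_id in time-course table", call. = FALSE)
  ex <- c("expr_0", "expr_2.5", "expr_4", "expr_24")
  if (any(as.matrix(df[ex]) < 0))
    stop("expression values must be non-negative", call. = FALSE)
  df$fc24 <- ifelse(df$expr_0 > 0, df$expr_24 / df$expr_0, NA_real_)
  df
}

#' Read a gene curation table
#'
#' Expects columns `gene_id`, `verdict`, `functional_group`, `location`.
#' Verdicts are `keep`, `dismiss_metabolic`, `dismiss_non_immune` or
#' `dismiss_unknown`.
#'
#' @param path Path to the TSV.
#' @return A data.frame, one row per gene.
#' @export
read_curation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("gene_id", "verdict", "functional_group", "location")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("curation table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- df[req]
  verdicts <- c("keep", "dismiss_metabolic", "dismiss_non_immune",
                "dismiss_unknown")
  if (!all(df$verdict %in% verdicts))
    stop("unknown curation verdict(s): ",
         paste(setdiff(unique(df$verdict), verdicts), collapse = ", "),
         call. = FALSE)
  locs <- c("plasma_membrane", "secreted", "cytoplasm", "nucleus")
  df$location <- .na_dot(df$location)
  if (!all(df$location %in% c(locs, NA)))
    stop("unknown protein location(s)", call. = FALSE)
  if (anyDuplicated(df$gene_id))
    stop("duplicated gene_id in curation table", call. = FALSE)
  df
}

.report_columns <- c(
  "gene_id", "consensus_support", "kind", "constellation", "distance_kb",
  "super_enhancer", "enhancer_ligand_dependent", "tss_ligand_dependent",
  "epigenome_class", "primary_target", "tertial_basal", "tertial_fc",
  "tertial_p", "transcriptome_group", "verdict", "functional_group",
  "location")

#' Write integrated gene reports
#'
#' Emits the per-gene report as a TSV whose columns mirror the published
#' epigenome and transcriptome classification tables, plus a JSON sidecar
#' (`<path>.json`) recording the configuration and input provenance. Output
#' is byte-deterministic for identical inputs and configuration.
#'
#' @param reports A report data.frame from [build_reports()] (may be empty).
#' @param path Output TSV path.
#' @param cfg A [pipeline_config()] object recorded in the sidecar.
#' @param inputs Optional character vector of input file paths; their md5
#'   checksums are recorded in the sidecar.
#' @return Invisibly, `path`.
#' @export
write_report <- function(reports, path, cfg = pipeline_config(),
                         inputs = NULL) {
  if (nrow(reports)) {
    missing <- setdiff(.report_columns, names(reports))
    if (length(missing))
      stop("report is missing column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    out <- reports[.report_columns]
  } else {
    out <- as.data.frame(stats::setNames(
      replicate(length(.report_columns), character(0), simplify = FALSE),
      .report_columns))
  }
  for (col in c("super_enhancer", "enhancer_ligand_dependent",
                "tss_ligand_dependent", "primary_target")) {
    if (is.logical(out[[col]]))
      out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                           ifelse(out[[col]], "yes", "no"))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  sidecar <- list(config = unclass(cfg))
  if (!is.null(inputs)) {
    sums <- tools::md5sum(inputs)
    sidecar$inputs <- lapply(seq_along(inputs), function(i)
      list(path = basename(inputs[i]), md5 = unname(sums[i])))
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read integrated gene reports
#'
#' Inverse of [write_report()]; yes/no columns come back as logicals.
#'
#' @param path Path to a report TSV.
#' @return A report data.frame.
#' @export
read_report <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  for (col in c("super_enhancer", "enhancer_ligand_dependent",
                "tss_ligand_dependent", "primary_target")) {
    if (col %in% names(df)) df[[col]] <- df[[col]] == "yes"
  }
  df
}
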