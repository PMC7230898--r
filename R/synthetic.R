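## Seeded generators of synthetic inputs with known ground truth for every
## pipeline stage: multi-dataset differential-expression tables with planted
## consensus members, peak landscapes realizing planted enhancer
## architectures, and response time courses with planted dynamics.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate differential-expression tables with planted consensus members
#'
#' Emits one table per dataset such that each planted gene is significant
#' (`padj < alpha`) in exactly its requested number of datasets, while
#' background genes are significant in fewer than `cfg$consensus_k`
#' datasets. The k-of-n consensus on these tables (strategy
#' `unfiltered_significant`) therefore recovers exactly the planted genes
#' with support >= k.
#'
#' @param n_datasets Number of datasets.
#' @param n_genes Total number of genes (background genes are generated to
#'   fill up beyond the planted ones).
#' @param planted Named integer vector gene id -> support count (number of
#'   datasets in which the gene must be significant).
#' @param cfg A [pipeline_config()].
#' @param seed Integer seed.
#' @return A named list of differential-expression data.frames.
#' @export
gen_de_tables <- function(n_datasets, n_genes, planted,
                          cfg = pipeline_config(), seed = cfg$seed) {
  if (any(planted > n_datasets))
    stop("planted support exceeds the number of datasets", call. = FALSE)
  if (any(planted < 0)) stop("support counts must be >= 0", call. = FALSE)
  if (length(planted) > n_genes)
    stop("'n_genes' must cover the planted genes", call. = FALSE)
  .with_seed(seed, {
    n_bg <- n_genes - length(planted)
    bg_ids <- sprintf("BG%05d", seq_len(n_bg))
    bg_support <- sample(0:(min(cfg$consensus_k, n_datasets) - 1L),
                         n_bg, replace = TRUE)
    genes <- c(names(planted), bg_ids)
    support <- c(unname(planted), bg_support)
    in_sets <- lapply(support, function(s) sample(n_datasets, s))
    ds_ids <- sprintf("DS%d", seq_len(n_datasets))
    tables <- lapply(seq_len(n_datasets), function(d) {
      hit <- vapply(in_sets, function(s) d %in% s, logical(1))
      padj <- ifelse(hit,
                     stats::runif(length(genes), 1e-6, cfg$alpha * 0.9),
                     stats::runif(length(genes), cfg$alpha * 1.5, 1))
      data.frame(
        gene_id = genes,
        dataset_id = ds_ids[d],
        basal = stats::rlnorm(length(genes), meanlog = 5, sdlog = 1.5),
        log2fc = ifelse(hit, stats::rnorm(length(genes), 2, 0.5),
                        stats::rnorm(length(genes), 0, 0.3)),
        pvalue = padj * stats::runif(length(genes), 0.1, 1),
        padj = padj,
        stringsAsFactors = FALSE
      )
    })
    stats::setNames(tables, ds_ids)
  })
}

#' Random enhancer-architecture specifications
#'
#' Draws per-gene ground-truth architectures: super-enhancers (three
#' classified VDR sites within the stitching window, at least one strong
#' persistent/transient site), single strong enhancers, or no qualifying
#' enhancer. Combinations that cannot be realized unambiguously (a
#' ligand-dependent enhancer inside a non-dependent TSS window) are never
#' drawn.
#'
#' @param n Number of specs.
#' @param seed Integer seed.
#' @return A data.frame with columns `gene_id`, `kind`, `constellation`,
#'   `ligand_dependent`, `tss_ligand_dependent`, `distance_kb`.
#' @export
gen_architecture_specs <- function(n, seed = 1L) {
  .with_seed(seed, {
    kind <- sample(c("super", "single", "none"), n, replace = TRUE,
                   prob = c(0.4, 0.4, 0.2))
    specs <- lapply(seq_len(n), function(i) {
      k <- kind[i]
      dep <- stats::runif(1) < 0.5
      tss_dep <- stats::runif(1) < 0.5
      if (k == "super") {
        nsite <- sample(3:5, 1L)
        cls <- sample(c("P", "T", "24"), nsite, replace = TRUE)
        if (!any(cls %in% c("P", "T")))
          cls[1L] <- sample(c("P", "T"), 1L)
        cls <- cls[order(match(cls, c("P", "T", "24")))]
        con <- paste(cls, collapse = "-")
        dist <- round(stats::runif(1, 15, 500), 1)
      } else if (k == "single") {
        con <- sample(c("P", "T"), 1L)
        if (stats::runif(1) < 0.2) {
          dist <- 0
          if (dep) tss_dep <- TRUE  # enhancer inside the TSS window
        } else dist <- round(stats::runif(1, 0.4, 500), 1)
      } else {
        con <- NA_character_
        dep <- FALSE
        dist <- NA_real_
      }
      data.frame(gene_id = sprintf("SYN%04d", i), kind = k,
                 constellation = con, ligand_dependent = dep,
                 tss_ligand_dependent = tss_dep, distance_kb = dist,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, specs)
  })
}

#' Default anchors for synthetic genes
#'
#' One pseudo-chromosome per gene with the TSS at 2 Mb, so windows never
#' interfere across genes.
#'
#' @param gene_ids Character vector of gene ids.
#' @return A gene-anchor data.frame.
#' @export
synthetic_anchors <- function(gene_ids) {
  data.frame(gene_id = gene_ids,
             chrom = paste0("chr_", gene_ids),
             tss = 2000000L,
             strand = rep(c("+", "-"), length.out = length(gene_ids)),
             stringsAsFactors = FALSE)
}

## one peak-table row (0-based half-open)
.peak_row <- function(chrom, start0, end0, name, score, assay, condition,
                      site_class = NA, strength = NA, diff_pvalue = NA) {
  data.frame(chrom = chrom, start = start0, end = end0, name = name,
             score = score, strand = ".", assay = assay,
             condition = condition, site_class = site_class,
             strength = strength, diff_pvalue = diff_pvalue,
             stringsAsFactors = FALSE)
}

## peaks realizing one architecture spec around one anchor
.peakscape_one <- function(anchor, spec, cfg, side) {
  tss <- anchor$tss
  chrom <- anchor$chrom
  g <- anchor$gene_id
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r
  ns <- 0.5   # non-significant differential p-value
  sig <- 0.01

  ## TSS furniture: active-TSS mark left of the TSS inside the core
  ## promoter (carries the TSS ligand-dependency flag), accessible
  ## chromatin and active chromatin across the promoter.
  tssdep <- isTRUE(spec$tss_ligand_dependent)
  add(.peak_row(chrom, tss - 180, tss - 20, paste0(g, "_k4_tss"), 12,
                "H3K4me3", "ligand", diff_pvalue = if (tssdep) sig else ns))
  add(.peak_row(chrom, tss - 180, tss - 20, paste0(g, "_k4_tss_s"), 10,
                "H3K4me3", "solvent"))
  add(.peak_row(chrom, tss - 250, tss + 250, paste0(g, "_acc_tss"), 8,
                "accessibility", "ligand", diff_pvalue = ns))
  add(.peak_row(chrom, tss - 400, tss + 400, paste0(g, "_k27_tss"), 9,
                "H3K27ac", "ligand", diff_pvalue = ns))

  if (spec$kind == "super") {
    cls <- strsplit(spec$constellation, "-", fixed = TRUE)[[1L]]
    k <- length(cls)
    if (k < cfg$se_min_sites)
      stop("super-enhancer spec needs >= ", cfg$se_min_sites,
           " site classes: ", spec$gene_id, call. = FALSE)
    if (!any(cls %in% c("P", "T")))
      stop("super-enhancer spec needs a persistent or transient site: ",
           spec$gene_id, call. = FALSE)
    d <- as.integer(round(spec$distance_kb * 1000)) * side
    half <- 8000L
    centers <- round(seq(d - half, d + half, length.out = k))
    ## exactly one strong persistent/transient site, placed at the
    ## TSS-distal end so no sub-cluster can qualify closer to the TSS
    distal <- if (side > 0) k else 1L
    pt <- which(cls %in% c("P", "T"))
    ord <- seq_len(k)
    if (!(distal %in% pt)) {         # move a P/T class to the distal slot
      swap <- pt[1L]
      ord[c(swap, distal)] <- ord[c(distal, swap)]
    }
    cls <- cls[ord]
    strength <- rep("weak", k)
    strength[distal] <- "strong"
    dep_site <- distal
    for (i in seq_len(k)) {
      add(.peak_row(chrom, tss + centers[i] - 100, tss + centers[i] + 100,
                    sprintf("%s_vdr%d", g, i), 20, "VDR", "ligand",
                    site_class = cls[i], strength = strength[i],
                    diff_pvalue = if (spec$ligand_dependent && i == dep_site)
                      sig else ns))
    }
    add(.peak_row(chrom, tss + d - half - 600, tss + d + half + 600,
                  paste0(g, "_k27_enh"), 15, "H3K27ac", "ligand",
                  diff_pvalue = ns))
    add(.peak_row(chrom, tss + d - half - 600, tss + d + half + 600,
                  paste0(g, "_k27_enh_s"), 14, "H3K27ac", "solvent"))
  } else if (spec$kind == "single") {
    if (!spec$constellation %in% c("P", "T"))
      stop("single-enhancer spec needs class P or T: ", spec$gene_id,
           call. = FALSE)
    if (spec$distance_kb == 0) {
      if (spec$ligand_dependent && !spec$tss_ligand_dependent)
        stop("contradictory spec for ", spec$gene_id,
             ": a ligand-dependent enhancer inside the TSS window forces ",
             "TSS ligand-dependency", call. = FALSE)
      s0 <- tss; e0 <- tss + 160   # overlaps the core promoter
    } else {
      c0 <- tss + as.integer(round(spec$distance_kb * 1000)) * side
      s0 <- c0 - 100; e0 <- c0 + 100
    }
    add(.peak_row(chrom, s0, e0, paste0(g, "_vdr1"), 25, "VDR", "ligand",
                  site_class = spec$constellation, strength = "strong",
                  diff_pvalue = if (spec$ligand_dependent) sig else ns))
    add(.peak_row(chrom, s0 - 400, e0 + 400, paste0(g, "_k27_enh"), 13,
                  "H3K27ac", "ligand", diff_pvalue = ns))
  } else {
    ## no qualifying enhancer: a lone weak 24-h-only site
    c0 <- tss + 150000L * side
    add(.peak_row(chrom, c0 - 100, c0 + 100, paste0(g, "_vdr_decoy"), 4,
                  "VDR", "ligand", site_class = "24", strength = "weak",
                  diff_pvalue = ns))
  }
  do.call(rbind, rows)
}

#' Generate peak tracks realizing planted enhancer architectures
#'
#' For every specification, emits VDR sites realizing the constellation
#' (a stitched cluster within the super-enhancer window, or a lone strong
#' persistent/transient site at the given distance), continuous H3K27ac
#' across super-enhancer spans, active-TSS and accessibility furniture,
#' and differential p-values encoding the planted ligand-dependency flags.
#' [profile_gene()] recovers every planted architecture exactly on a
#' noise-free landscape.
#'
#' @param anchors Gene-anchor data.frame covering all spec genes.
#' @param specs An architecture-spec data.frame (see
#'   [gen_architecture_specs()]).
#' @param cfg A [pipeline_config()].
#' @param seed Integer seed (used only for upstream/downstream placement).
#' @return A sorted peak `GRanges`.
#' @export
gen_peakscape <- function(anchors, specs, cfg = pipeline_config(),
                          seed = cfg$seed) {
  missing <- setdiff(specs$gene_id, anchors$gene_id)
  if (length(missing))
    stop("specs reference unknown anchors: ",
         paste(missing, collapse = ", "), call. = FALSE)
  .with_seed(seed, {
    sides <- sample(c(-1L, 1L), nrow(specs), replace = TRUE)
    tabs <- lapply(seq_len(nrow(specs)), function(i) {
      spec <- specs[i, ]
      anchor <- anchors[anchors$gene_id == spec$gene_id, ]
      .peakscape_one(anchor, spec, cfg, sides[i])
    })
    as_peaks(do.call(rbind, tabs))
  })
}

#' Random time-course dynamics specifications
#'
#' Draws per-gene ground truth for the transcriptome classification:
#' steepness group, primary/secondary status, basal level and 24 h fold
#' change, with group-consistent parameters.
#'
#' @param n Number of specs.
#' @param seed Integer seed.
#' @return A data.frame with columns `gene_id`, `group`, `primary`,
#'   `basal_level`, `fc24`, `noise_sd`.
#' @export
gen_dynamics_specs <- function(n, seed = 1L) {
  .with_seed(seed, {
    group <- sample(1:3, n, replace = TRUE)
    fc24 <- ifelse(group == 1L, stats::runif(n, 5, 10),
                   ifelse(group == 2L, stats::runif(n, 2.2, 5),
                          stats::runif(n, 1.3, 3)))
    data.frame(
      gene_id = sprintf("DYN%04d", seq_len(n)),
      group = group,
      primary = stats::runif(n) < 0.8,
      basal_level = stats::rlnorm(n, meanlog = 5, sdlog = 1),
      fc24 = fc24,
      noise_sd = 0,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate time-course tables from dynamics specifications
#'
#' Builds expression trajectories over 0/2.5/4/24 h whose late steepness
#' `log2(expr_24/expr_4)` falls inside the requested group's band, with
#' early p-values consistent with the primary flag and multiplicative
#' lognormal noise of the requested standard deviation.
#'
#' @param specs A dynamics-spec data.frame (see [gen_dynamics_specs()]).
#' @param cfg A [pipeline_config()].
#' @param seed Integer seed.
#' @return A time-course data.frame in the [read_timecourse()] layout.
#' @export
gen_timecourse <- function(specs, cfg = pipeline_config(),
                           seed = cfg$seed) {
  lo <- cfg$group_theta_low
  hi <- cfg$group_theta_high
  .with_seed(seed, {
    rows <- lapply(seq_len(nrow(specs)), function(i) {
      sp <- specs[i, ]
      band <- switch(sp$group,
                     c(hi + 0.1, hi + 1.2),
                     c(lo + 0.05, hi - 0.05),
                     c(lo * 0.05, lo * 0.85))
      if (isTRUE(sp$primary))
        band[2L] <- min(band[2L], log2(sp$fc24) - 0.05)
      if (band[2L] <= band[1L])
        stop("contradictory dynamics spec for ", sp$gene_id,
             ": fold change too small for group ", sp$group,
             " with a primary-target response", call. = FALSE)
      s <- stats::runif(1, band[1L], band[2L])
      e0 <- sp$basal_level
      e24 <- e0 * sp$fc24
      e4 <- e24 / 2^s
      e2.5 <- if (e4 > e0) e0 + 0.4 * (e4 - e0) else e0
      expr <- c(e0, e2.5, e4, e24) *
        exp(stats::rnorm(4, 0, sp$noise_sd))
      data.frame(
        gene_id = sp$gene_id,
        expr_0 = expr[1L], `expr_2.5` = expr[2L], expr_4 = expr[3L],
        expr_24 = expr[4L],
        `p_2.5` = if (isTRUE(sp$primary)) 0.3 else 0.6,
        p_4 = if (isTRUE(sp$primary)) 0.001 else 0.3,
        p_24 = 0.001,
        check.names = FALSE,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    out$fc24 <- ifelse(out$expr_0 > 0, out$expr_24 / out$expr_0, NA_real_)
    out
  })
}

#' Write a complete synthetic input directory
#'
#' Materializes one seeded synthetic study on disk: per-dataset
#' differential-expression TSVs, a combined peak BED, a TSS annotation TSV,
#' a time-course TSV and a ground-truth JSON.
#'
#' @param dir Output directory (created if needed).
#' @param n_datasets,n_genes,planted Passed to [gen_de_tables()].
#' @param n_arch,n_dyn Numbers of architecture and dynamics specs.
#' @param cfg A [pipeline_config()].
#' @param seed Integer seed.
#' @return Invisibly, the list of written paths.
#' @export
simulate_inputs <- function(dir, n_datasets = 5L, n_genes = 200L,
                            planted = NULL, n_arch = 20L, n_dyn = 20L,
                            cfg = pipeline_config(), seed = cfg$seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(planted))
    planted <- stats::setNames(
      rep(c(n_datasets, cfg$consensus_k), each = 3L),
      sprintf("PLANT%02d", 1:6))
  de <- gen_de_tables(n_datasets, n_genes, planted, cfg, seed)
  arch <- gen_architecture_specs(n_arch, seed + 1L)
  anchors <- synthetic_anchors(arch$gene_id)
  peaks <- gen_peakscape(anchors, arch, cfg, seed + 2L)
  dyn <- gen_dynamics_specs(n_dyn, seed + 3L)
  tc <- gen_timecourse(dyn, cfg, seed + 4L)
  paths <- list()
  for (nm in names(de)) {
    p <- file.path(dir, paste0("de_", nm, ".tsv"))
    df <- de[[nm]]
    names(df)[names(df) == "basal"] <- "baseMean"
    names(df)[names(df) == "log2fc"] <- "log2FoldChange"
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[paste0("de_", nm)]] <- p
  }
  paths$peaks <- write_peaks(peaks, file.path(dir, "peaks.bed"))
  utils::write.table(anchors, file.path(dir, "tss.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$tss <- file.path(dir, "tss.tsv")
  utils::write.table(tc[setdiff(names(tc), "fc24")],
                     file.path(dir, "timecourse.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths$timecourse <- file.path(dir, "timecourse.tsv")
  jsonlite::write_json(
    list(planted = as.list(planted), architecture = arch, dynamics = dyn,
         seed = seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  paths$truth <- file.path(dir, "truth.json")
  invisible(paths)
}
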