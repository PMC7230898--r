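# Independent brute-force oracles and small constructors used across tests.
# The oracles share no code with the implementation: plain data.frames in
# 0-based half-open coordinates and exhaustive loops.

# quick peak table row(s); 0-based half-open
pk <- function(chrom, start, end, assay = "VDR", condition = "ligand",
               site_class = NA, strength = NA, diff_pvalue = NA,
               name = NULL, score = 1) {
  n <- max(length(chrom), length(start), length(end))
  if (length(start) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0),
                      assay = character(0), condition = character(0),
                      site_class = character(0), strength = character(0),
                      diff_pvalue = numeric(0), stringsAsFactors = FALSE))
  data.frame(chrom = chrom, start = start, end = end,
             name = if (is.null(name)) sprintf("pk%03d", seq_len(n)) else name,
             score = score, strand = ".", assay = assay,
             condition = condition, site_class = site_class,
             strength = strength, diff_pvalue = diff_pvalue,
             stringsAsFactors = FALSE)
}

anchor1 <- function(gene_id = "G1", chrom = "chr1", tss = 2000000L,
                    strand = "+") {
  data.frame(gene_id = gene_id, chrom = chrom, tss = as.integer(tss),
             strand = strand, stringsAsFactors = FALSE)
}

# brute-force overlap scan of a 0-based half-open window [tss-r, tss+r)
oracle_window <- function(df, chrom, tss, r) {
  hit <- df$chrom == chrom & df$start < tss + r & df$end > tss - r
  df[hit, , drop = FALSE]
}

# independent interval merge: intervals (start, end) 0-based half-open,
# gaps of at most max_gap bridged; returns TRUE iff one merged interval
# covers [s, e)
oracle_continuity <- function(starts, ends, s, e, max_gap) {
  if (length(starts) == 0L) return(FALSE)
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1L]; me <- ends[1L]
  merged <- list()
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] - me <= max_gap) {
      me <- max(me, ends[i])
    } else {
      merged[[length(merged) + 1L]] <- c(ms, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  merged[[length(merged) + 1L]] <- c(ms, me)
  any(vapply(merged, function(iv) iv[1L] <= s && iv[2L] >= e, logical(1)))
}

# exhaustive subset-enumeration super-enhancer oracle over a VDR site table
# (0-based columns start, end, site_class, strength) and an H3K27ac table;
# returns NULL or list(start, end) of the selected span
oracle_super <- function(vdr, k27, tss, w = 20000, min_sites = 3,
                         max_gap = 1000) {
  n <- nrow(vdr)
  if (n < min_sites) return(NULL)
  best <- NULL
  for (size in min_sites:n) {
    for (idx in utils::combn(n, size, simplify = FALSE)) {
      s <- min(vdr$start[idx]); e <- max(vdr$end[idx])
      if (e - s > w) next
      strong <- any(vdr$strength[idx] == "strong" &
                    vdr$site_class[idx] %in% c("P", "T"), na.rm = TRUE)
      if (!strong) next
      if (!oracle_continuity(k27$start, k27$end, s, e, max_gap)) next
      hull <- sum(vdr$start >= s & vdr$end <= e)
      cand <- list(start = s, end = e, dist = abs((s + e) / 2 - tss),
                   size = hull)
      if (is.null(best) || cand$dist < best$dist ||
          (cand$dist == best$dist && cand$size > best$size) ||
          (cand$dist == best$dist && cand$size == best$size &&
           cand$start < best$start))
        best <- cand
    }
  }
  best
}

# random VDR/H3K27ac landscape around a TSS for oracle-equivalence tests
random_landscape <- function(tss = 2000000L, max_sites = 12L) {
  n <- sample(3:max_sites, 1L)
  centers <- sort(round(tss + runif(n, -30000, 30000)))
  vdr <- pk("chrR", centers - 100, centers + 100,
            site_class = sample(c("P", "T", "24"), n, replace = TRUE),
            strength = sample(c("strong", "weak"), n, replace = TRUE),
            name = sprintf("v%02d", seq_len(n)))
  nk <- sample(0:6, 1L)
  if (nk > 0L) {
    ks <- round(tss + runif(nk, -32000, 28000))
    kw <- round(runif(nk, 2000, 15000))
    k27 <- pk("chrR", ks, ks + kw, assay = "H3K27ac",
              name = sprintf("k%02d", seq_len(nk)))
  } else {
    k27 <- pk("chrR", integer(0), integer(0), assay = "H3K27ac")
  }
  list(vdr = vdr, k27 = k27)
}
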