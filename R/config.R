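#' Pipeline configuration
#'
#' Collects every tunable threshold of the target-gene pipeline in one
#' validated object. Defaults encode the published analysis conditions:
#' top-100 ranking lists, 4-of-5 consensus, p < 0.05 significance, the
#' super-enhancer rule (three VDR sites within 20 kb, at least one strong
#' persistent/transient site, continuous H3K27ac), a +/- 1 Mb search radius
#' around the TSS, and the late-steepness thresholds of the transcriptome
#' grouping.
#'
#' @param top_n Number of genes retained per ranking criterion in the
#'   top-N union filter.
#' @param consensus_k Minimum number of datasets a gene must appear in to
#'   enter the consensus set.
#' @param alpha Significance level used for adjusted/differential p-values.
#' @param se_window_bp Maximal extent (first site start to last site end, bp)
#'   of a VDR site cluster eligible as a super-enhancer.
#' @param se_min_sites Minimum number of VDR sites in a super-enhancer.
#' @param h3k27ac_max_gap_bp Maximal gap (bp) bridged when merging H3K27ac
#'   intervals for the continuity requirement.
#' @param tss_window_bp Half-width (bp) of the core-promoter window used to
#'   call direct TSS binding (distance 0) and to evaluate TSS ligand
#'   dependency.
#' @param search_radius_bp Half-width (bp) of the enhancer search window
#'   around each TSS.
#' @param strength_quantile Score quantile above which an unlabeled VDR peak
#'   is called strong.
#' @param group_theta_low,group_theta_high Late-steepness thresholds
#'   (log2 scale of the 4 h to 24 h expression ratio) separating transcriptome
#'   groups 3/2 and 2/1.
#' @param seed Integer seed for the synthetic-data generators.
#'
#' @return An object of class `vdr_config` (a named list).
#' @examples
#' cfg <- pipeline_config(consensus_k = 4)
#' cfg$se_window_bp
#' @export
pipeline_config <- function(top_n = 100L,
                            consensus_k = 4L,
                            alpha = 0.05,
                            se_window_bp = 20000L,
                            se_min_sites = 3L,
                            h3k27ac_max_gap_bp = 1000L,
                            tss_window_bp = 200L,
                            search_radius_bp = 1000000L,
                            strength_quantile = 0.75,
                            group_theta_low = 0.3,
                            group_theta_high = 1.0,
                            seed = 1L) {
  cfg <- list(
    top_n = as.integer(top_n),
    consensus_k = as.integer(consensus_k),
    alpha = as.numeric(alpha),
    se_window_bp = as.integer(se_window_bp),
    se_min_sites = as.integer(se_min_sites),
    h3k27ac_max_gap_bp = as.integer(h3k27ac_max_gap_bp),
    tss_window_bp = as.integer(tss_window_bp),
    search_radius_bp = as.integer(search_radius_bp),
    strength_quantile = as.numeric(strength_quantile),
    group_theta_low = as.numeric(group_theta_low),
    group_theta_high = as.numeric(group_theta_high),
    seed = as.integer(seed)
  )
  num <- vapply(cfg, function(x) x[[1L]], numeric(1))
  if (any(!is.finite(num)))
    stop("all configuration values must be finite", call. = FALSE)
  pos <- setdiff(names(cfg), "seed")
  if (any(num[pos] <= 0))
    stop("configuration values must be positive: ",
         paste(pos[num[pos] <= 0], collapse = ", "), call. = FALSE)
  if (cfg$strength_quantile >= 1)
    stop("'strength_quantile' must lie in (0, 1)", call. = FALSE)
  if (cfg$group_theta_high < cfg$group_theta_low)
    stop("'group_theta_high' must be >= 'group_theta_low'", call. = FALSE)
  structure(cfg, class = "vdr_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to the
#' [pipeline_config()] defaults.
#'
#' @param path Path to a YAML file of configuration keys.
#' @return A `vdr_config` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, vals)
}

#' @export
print.vdr_config <- function(x, ...) {
  cat("vdrtargets pipeline configuration\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  invisible(x)
}
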