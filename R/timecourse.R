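## Classification of ligand-response time courses (0, 2.5, 4, 24 h):
## primary vs secondary targets, tertials for basal activity, inducibility
## and sensitivity, and steepness groups 1-3.

#' Primary target call
#'
#' A gene is a primary target when it shows a statistically significant
#' increase in expression within 4 h of ligand stimulation, i.e. at the
#' 2.5 h or the 4 h time point.
#'
#' @param profile A one-row time-course record (columns `expr_0`,
#'   `expr_2.5`, `expr_4`, `p_2.5`, `p_4`).
#' @param alpha Significance level.
#' @return Logical.
#' @export
is_primary_target <- function(profile, alpha = 0.05) {
  req <- c("expr_0", "expr_2.5", "expr_4", "p_2.5", "p_4")
  if (!all(req %in% names(profile)) ||
      anyNA(unlist(profile[req], use.names = FALSE)))
    stop("early time points (2.5 h, 4 h) are required", call. = FALSE)
  (profile$expr_2.5 > profile$expr_0 & profile$p_2.5 < alpha) ||
    (profile$expr_4 > profile$expr_0 & profile$p_4 < alpha)
}

#' Rank-based tertials
#'
#' Splits the analyzed gene set into top/mid/low thirds by rank. When the
#' set size is not divisible by three, the excess goes to the top tertial
#' first, then mid. For p-value-like quantities set `higher_is_top =
#' FALSE` so the smallest values rank top. Ties are broken by gene id.
#'
#' @param values A named numeric vector (names = gene ids, length >= 3).
#' @param higher_is_top Whether large values rank top.
#' @return A named character vector (`"top"`, `"mid"`, `"low"`) over the
#'   same genes.
#' @export
tertile_assign <- function(values, higher_is_top = TRUE) {
  n <- length(values)
  if (n < 3L) stop("at least 3 genes are required", call. = FALSE)
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop("'values' must carry unique gene names", call. = FALSE)
  ord <- order(if (higher_is_top) -values else values, names(values),
               method = "radix")
  base <- n %/% 3L
  rem <- n %% 3L
  sizes <- c(top = base + (rem >= 1L), mid = base + (rem >= 2L), low = base)
  labels <- rep(c("top", "mid", "low"), times = sizes)
  stats::setNames(labels, names(values)[ord])[names(values)]
}

#' Steepness group of a time course
#'
#' Operationalizes curve steepness as the late log-ratio
#' `s = log2(expr_24 / expr_4)`: group 3 ("no major increase after 4 h")
#' when `s < group_theta_low`, group 1 (steepest curves) when
#' `s >= group_theta_high`, group 2 (intermediate) otherwise. The rule is
#' unit-free and monotone in the 24 h expression.
#'
#' @param profile A one-row time-course record (`expr_4`, `expr_24`).
#' @param cfg A [pipeline_config()] supplying the two thresholds.
#' @return Integer group 1, 2 or 3.
#' @export
steepness_group <- function(profile, cfg = pipeline_config()) {
  e4 <- profile$expr_4
  if (e4 <= 0) {
    warning("expr_4 is zero; using a small positive floor", call. = FALSE)
    e4 <- max(profile$expr_24, 1) * 1e-6
  }
  s <- log2(profile$expr_24 / e4)
  if (s < cfg$group_theta_low) 3L
  else if (s >= cfg$group_theta_high) 1L
  else 2L
}

#' Classify a set of time courses
#'
#' Composes the primary-target call, the three tertials (basal activity:
#' higher is top; inducibility, i.e. fold change at 24 h: higher is top;
#' sensitivity, i.e. p-value at 24 h: lower is top) and the steepness
#' group, for every gene of the analyzed set. Tertials are computed within
#' this set.
#'
#' @param profiles A time-course data.frame from [read_timecourse()]
#'   (>= 3 genes).
#' @param cfg A [pipeline_config()].
#' @return A data.frame with columns `gene_id`, `primary_target`,
#'   `tertial_basal`, `tertial_fc`, `tertial_p`, `transcriptome_group`,
#'   plus the underlying `fc24` and late steepness `s_late`.
#' @export
classify_transcriptome <- function(profiles, cfg = pipeline_config()) {
  if (nrow(profiles) < 3L)
    stop("at least 3 profiles are required", call. = FALSE)
  if (anyDuplicated(profiles$gene_id))
    stop("duplicated gene_id in profiles", call. = FALSE)
  if (!"fc24" %in% names(profiles))
    profiles$fc24 <- ifelse(profiles$expr_0 > 0,
                            profiles$expr_24 / profiles$expr_0, NA_real_)
  g <- profiles$gene_id
  basal <- stats::setNames(profiles$expr_0, g)
  fc24 <- stats::setNames(profiles$fc24, g)
  p24 <- stats::setNames(profiles$p_24, g)
  t_basal <- tertile_assign(basal, higher_is_top = TRUE)
  t_fc <- tertile_assign(fc24, higher_is_top = TRUE)
  t_p <- tertile_assign(p24, higher_is_top = FALSE)
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    pr <- profiles[i, ]
    e4 <- if (pr$expr_4 > 0) pr$expr_4 else max(pr$expr_24, 1) * 1e-6
    data.frame(
      gene_id = pr$gene_id,
      primary_target = is_primary_target(pr, cfg$alpha),
      tertial_basal = unname(t_basal[pr$gene_id]),
      tertial_fc = unname(t_fc[pr$gene_id]),
      tertial_p = unname(t_p[pr$gene_id]),
      transcriptome_group = steepness_group(pr, cfg),
      fc24 = pr$fc24,
      s_late = log2(pr$expr_24 / e4),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
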