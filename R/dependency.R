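#' Classify cell lines by gene copy-number score
#'
#' A line is `amplified` when its copy-number score is >= 2.5, `diploid` when
#' the score lies in `[1.5, 2.5)` (the 2.5 boundary belongs to the amplified
#' band so the bands stay disjoint), and `excluded` otherwise; missing scores
#' are excluded.
#'
#' @param cn_score Numeric vector of per-line copy-number scores (vectorized).
#' @param amp_cutoff Lower bound of the amplified band (default 2.5).
#' @param dip_low Lower bound of the diploid band (default 1.5).
#' @return Character vector in \{"amplified", "diploid", "excluded"\}.
#' @export
classify_cell_lines <- function(cn_score, amp_cutoff = 2.5, dip_low = 1.5) {
  out <- rep("excluded", length(cn_score))
  out[!is.na(cn_score) & cn_score >= amp_cutoff] <- "amplified"
  out[!is.na(cn_score) & cn_score >= dip_low & cn_score < amp_cutoff] <- "diploid"
  out
}

#' Dependency contrast between amplified and diploid cell lines
#'
#' Two-sided Wilcoxon rank-sum comparison of Chronos scores between the two
#' groups (exact enumeration when both groups have <= 10 untied values,
#' normal approximation with tie correction otherwise). The median difference
#' is `median(diploid) - median(amplified)`, so a positive value means
#' amplified lines are more dependent (more negative Chronos). The knockout
#' is flagged significant when `median_diff > median_diff_cut`, `p < alpha`
#' and both groups reach `min_group` lines.
#'
#' @param chronos Numeric vector of Chronos scores (NA dropped pairwise with
#'   `status`).
#' @param status Classification per line from [classify_cell_lines()].
#' @param min_group Minimum lines per arm (default 5); below it the result is
#'   emitted with `significant = FALSE` and a skip reason.
#' @param median_diff_cut Median-difference threshold (default 0.10).
#' @param alpha P-value threshold (default 0.05).
#' @param gene_id Optional label carried into the result row.
#' @return One-row data frame with the dependency-result columns.
#' @export
dependency_contrast <- function(chronos, status, min_group = 5,
                                median_diff_cut = 0.10, alpha = 0.05,
                                gene_id = NA_character_) {
  keep <- !is.na(chronos) & status %in% c("amplified", "diploid")
  amp <- chronos[keep & status == "amplified"]
  dip <- chronos[keep & status == "diploid"]
  n_amp <- length(amp); n_dip <- length(dip)
  if (n_amp < min_group || n_dip < min_group) {
    return(data.frame(gene_id = gene_id, n_amplified = n_amp, n_diploid = n_dip,
                      median_amplified = if (n_amp) stats::median(amp) else NA_real_,
                      median_diploid = if (n_dip) stats::median(dip) else NA_real_,
                      median_diff = NA_real_, p_value = NA_real_,
                      significant = FALSE,
                      reason = sprintf("group_too_small (amplified=%d, diploid=%d, min=%d)",
                                       n_amp, n_dip, min_group),
                      stringsAsFactors = FALSE))
  }
  md <- stats::median(dip) - stats::median(amp)
  exact_ok <- n_amp <= 10 && n_dip <= 10 && !anyDuplicated(c(amp, dip))
  p <- suppressWarnings(
    stats::wilcox.test(amp, dip, exact = exact_ok, correct = TRUE)$p.value)
  data.frame(gene_id = gene_id, n_amplified = n_amp, n_diploid = n_dip,
             median_amplified = stats::median(amp),
             median_diploid = stats::median(dip),
             median_diff = md, p_value = p,
             significant = md > median_diff_cut && p < alpha,
             reason = "", stringsAsFactors = FALSE)
}

#' Screen genes for amplification-linked dependency
#'
#' For every requested gene, classifies the cell lines by that gene's
#' copy-number score and contrasts the Chronos scores of amplified versus
#' diploid lines. Missing values are dropped pairwise per gene.
#'
#' @param dep A [dependency_input()].
#' @param genes Gene symbols to screen (default: all shared genes).
#' @param amp_cutoff,dip_low Copy-number band bounds (defaults 2.5 / 1.5).
#' @inheritParams dependency_contrast
#' @return Dependency result data frame, one row per gene.
#' @export
dependency_screen <- function(dep, genes = NULL, amp_cutoff = 2.5, dip_low = 1.5,
                              min_group = 5, median_diff_cut = 0.10,
                              alpha = 0.05) {
  stopifnot(inherits(dep, "dependency_input"))
  if (is.null(genes)) genes <- colnames(dep$chronos)
  genes <- intersect(genes, colnames(dep$chronos))
  rows <- lapply(genes, function(g) {
    status <- classify_cell_lines(dep$cn_score[, g], amp_cutoff, dip_low)
    dependency_contrast(dep$chronos[, g], status, min_group = min_group,
                        median_diff_cut = median_diff_cut, alpha = alpha,
                        gene_id = g)
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    cols <- dependency_columns()
    structure(as.data.frame(lapply(cols, function(cl) vector(cl, 0)),
                            stringsAsFactors = FALSE), names = names(cols))
  }
  out$n_amplified <- as.integer(out$n_amplified)
  out$n_diploid <- as.integer(out$n_diploid)
  rownames(out) <- NULL
  out
}
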