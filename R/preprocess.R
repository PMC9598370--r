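#' Remove outlier samples by mean Spearman correlation
#'
#' Computes the square symmetric matrix of Spearman rank correlations between
#' all sample pairs on `log2(count + 1)` and removes, in a single pass, every
#' sample whose mean correlation with all other samples falls below `cor_cut`.
#' The log transform only collapses ties among high counts and is harmless for
#' a rank correlation; retained counts are never modified.
#'
#' @param expr An [expression_matrix()] with at least 3 samples.
#' @param cor_cut Mean-correlation threshold below which a sample is dropped
#'   (default 0.6).
#' @return List with `expr` (the filtered matrix) and `report`, a data frame
#'   of per-sample mean correlations and removal flags.
#' @export
remove_outlier_samples <- function(expr, cor_cut = 0.6) {
  stopifnot(inherits(expr, "expr_matrix"))
  n <- ncol(expr$counts)
  if (n < 3) stop("outlier screening needs at least 3 samples")
  rho <- stats::cor(log2(expr$counts + 1), method = "spearman")
  mean_cor <- (colSums(rho) - 1) / (n - 1)
  removed <- mean_cor < cor_cut
  if (all(removed))
    stop("all samples fall below cor_cut = ", cor_cut,
         "; lower the cutoff or inspect the cohort")
  report <- data.frame(sample_id = colnames(expr$counts),
                       mean_correlation = unname(mean_cor),
                       removed = unname(removed), stringsAsFactors = FALSE)
  list(expr = subset_expr(expr, samples = colnames(expr$counts)[!removed]),
       report = report)
}

#' Filter genes in the lowest quartile of mean expression
#'
#' Computes the per-gene mean across all samples and removes, in a single
#' pass, genes whose mean is strictly below the 25th percentile of gene means.
#' The quantile uses linear interpolation between order statistics
#' (`stats::quantile` type 7), a convention fixed for reproducibility.
#'
#' @param expr An [expression_matrix()] with at least 4 genes.
#' @param low_expr_quartile Quantile defining "low" (default 0.25).
#' @return The filtered `expr_matrix` (empty result permitted, with warning).
#' @export
filter_low_expression <- function(expr, low_expr_quartile = 0.25) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (nrow(expr$counts) < 4) stop("low-expression filtering needs >= 4 genes")
  means <- rowMeans(expr$counts)
  q1 <- stats::quantile(means, low_expr_quartile, type = 7, names = FALSE)
  keep <- means >= q1
  if (!any(keep)) warning("low-expression filter removed every gene")
  subset_expr(expr, genes = rownames(expr$counts)[keep])
}

#' Within-lane normalization on a gene-level covariate
#'
#' Removes the dependence of counts on gene GC content or length inside each
#' sample ("lane"). Genes are grouped into `n_bins` equal-frequency covariate
#' bins; within each sample the count distributions of the bins are
#' full-quantile normalized to their mean quantile profile, and the sample's
#' total count is then redistributed over genes (sample sums are preserved).
#' The mapping is monotone within each bin, so within-bin rank order is kept.
#'
#' @param expr An [expression_matrix()].
#' @param annotation A [gene_annotation()] providing the covariate for every
#'   retained gene.
#' @param covariate `"gc"` (uses `gc_fraction`) or `"length"` (interval width).
#' @param n_bins Number of equal-frequency covariate bins (default 10).
#' @return The normalized `expr_matrix` (same shape, non-negative values).
#' @export
normalize_within_lane <- function(expr, annotation, covariate = c("gc", "length"),
                                  n_bins = 10) {
  stopifnot(inherits(expr, "expr_matrix"))
  covariate <- match.arg(covariate)
  ann <- annotation[match(rownames(expr$counts), annotation$gene_id), ]
  cov <- if (covariate == "gc") ann$gc_fraction else ann$end - ann$start
  if (anyNA(cov))
    stop("covariate '", covariate, "' unavailable for ",
         sum(is.na(cov)), " gene(s); skip within-lane normalization ",
         "(set it to 'off') or complete the annotation")
  breaks <- unique(stats::quantile(cov, probs = seq(0, 1, length.out = n_bins + 1),
                                   type = 7, names = FALSE))
  if (length(breaks) < 3) return(expr)  # one effective bin: identity
  bin <- cut(cov, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  counts <- expr$counts
  out <- counts
  bins <- sort(unique(bin))
  for (s in seq_len(ncol(counts))) {
    x <- counts[, s]
    sorted <- lapply(bins, function(b) sort(x[bin == b]))
    # mean quantile profile over bins, evaluated on each gene's within-bin
    # rank position (type-7 grid)
    pos <- numeric(length(x))
    for (b in bins) {
      idx <- which(bin == b)
      nb <- length(idx)
      pos[idx] <- if (nb == 1) 0.5 else (rank(x[idx], ties.method = "average") - 1) / (nb - 1)
    }
    ref <- function(p) {
      vals <- vapply(sorted, function(sv) {
        nb <- length(sv)
        if (nb == 1) return(rep(sv, length(p)))
        stats::approx(seq(0, 1, length.out = nb), sv, xout = p, rule = 2)$y
      }, numeric(length(p)))
      if (is.null(dim(vals))) mean(vals) else rowMeans(vals)
    }
    y <- ref(pos)
    tot <- sum(x)
    if (sum(y) > 0 && tot > 0) y <- y * tot / sum(y)
    out[, s] <- y
  }
  structure(list(counts = out, condition = expr$condition), class = "expr_matrix")
}

#' Between-lane normalization across samples
#'
#' Removes between-sample sources of variation such as sequencing depth.
#' `full_quantile` maps every sample's count distribution onto the mean
#' quantile profile (via [limma::normalizeQuantiles()]); `upper_quartile`
#' rescales samples so all share the same 75th percentile (the mean of the
#' per-sample upper quartiles).
#'
#' @param expr An [expression_matrix()] with at least 2 samples.
#' @param method `"full_quantile"` (default) or `"upper_quartile"`.
#' @return The normalized `expr_matrix` (same shape, non-negative values).
#' @export
normalize_between_lane <- function(expr, method = c("full_quantile", "upper_quartile")) {
  stopifnot(inherits(expr, "expr_matrix"))
  method <- match.arg(method)
  counts <- expr$counts
  if (ncol(counts) < 2) stop("between-lane normalization needs >= 2 samples")
  zero <- colSums(counts) == 0
  if (any(zero))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero], collapse = ", "))
  if (method == "full_quantile") {
    out <- limma::normalizeQuantiles(counts, ties = TRUE)
    dimnames(out) <- dimnames(counts)
  } else {
    uq <- apply(counts, 2, stats::quantile, probs = 0.75, type = 7, names = FALSE)
    if (any(uq == 0))
      stop("75th percentile is zero for sample(s): ",
           paste(colnames(counts)[uq == 0], collapse = ", "))
    out <- sweep(counts, 2, mean(uq) / uq, `*`)
  }
  structure(list(counts = out, condition = expr$condition), class = "expr_matrix")
}
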