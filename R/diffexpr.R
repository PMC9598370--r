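#' Equalize library sizes by scaling to the geometric mean
#'
#' The conditional negative-binomial exact test assumes all samples share one
#' library size. Each sample's counts are therefore scaled to the geometric
#' mean of the observed library sizes and rounded to integers; the scaling
#' factors are reported.
#'
#' @param counts Integer matrix, genes x samples, column sums > 0.
#' @return List with `counts` (integer pseudo-counts), `factors` (per-sample
#'   scaling factors) and `target` (the common library size).
#' @export
equalize_library_sizes <- function(counts) {
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  target <- exp(mean(log(lib)))
  f <- target / lib
  pseudo <- round(sweep(counts, 2, f, `*`))
  storage.mode(pseudo) <- "integer"
  list(counts = pseudo, factors = f, target = target)
}

# conditional log-likelihood of the within-group splits given group totals,
# under NB with shared dispersion phi; y_groups is a list of genes x samples
# matrices (one per group)
cond_loglik <- function(phi, y_groups) {
  r <- 1 / phi
  ll <- 0
  for (y in y_groups) {
    n <- ncol(y)
    z <- rowSums(y)
    ll <- ll + sum(lgamma(y + r)) - nrow(y) * n * lgamma(r) +
      nrow(y) * lgamma(n * r) - sum(lgamma(z + n * r)) +
      sum(lgamma(z + 1)) - sum(lgamma(y + 1))
  }
  ll
}

# golden-section maximization of f on [lo, hi]
golden_section_max <- function(f, lo, hi, tol = 1e-3) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 >= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    }
  }
  (a + b) / 2
}

#' Estimate the common negative-binomial dispersion by conditional ML
#'
#' Maximizes, over a single shared dispersion `phi`, the sum over genes of the
#' log conditional probability of the within-group count splits given their
#' group totals, under a negative binomial with per-group mean and variance
#' `mu + phi * mu^2`. The maximization is a golden-section search on
#' `log10(phi)` in `[-4, 0.6]` (i.e. `phi` in about `[1e-4, 4]`) with
#' tolerance `1e-3`; a boundary hit is flagged in the result.
#'
#' @param counts Library-equalized integer pseudo-counts, genes x samples.
#' @param groups Two-level factor/character vector, one entry per sample;
#'   both groups need >= 2 samples.
#' @return List of class `dispersion_estimate`: `phi`, `loglik_at_phi`,
#'   `search_interval` (on phi scale) and `at_boundary`.
#' @export
estimate_common_dispersion <- function(counts, groups) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required")
  if (any(table(groups) < 2)) stop("each group needs >= 2 samples")
  if (all(counts == 0)) stop("all-zero count matrix: dispersion undefined")
  y_groups <- lapply(lev, function(g) counts[, groups == g, drop = FALSE])
  f <- function(l10) cond_loglik(10^l10, y_groups)
  lo <- -4; hi <- 0.6
  opt <- golden_section_max(f, lo, hi, tol = 1e-3)
  phi <- 10^opt
  structure(list(phi = phi, loglik_at_phi = f(opt),
                 search_interval = c(10^lo, 10^hi),
                 at_boundary = (opt - lo < 2e-3) || (hi - opt < 2e-3)),
            class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf("common dispersion phi = %.5f (conditional ML%s)\n", x$phi,
              if (x$at_boundary) ", at search boundary" else ""))
  invisible(x)
}

#' Negative-binomial exact test for a two-group count split
#'
#' Conditional on the total `T` of a gene's counts over both groups, the group-A
#' sum `S` follows `P(S = s | T) proportional to f(s; r_a) f(T - s; r_b)`,
#' where `f` is the negative-binomial mass with size `r_g = n_g / phi` (all
#' samples sharing one mean and one library size); at `phi = 0` this reduces
#' to `Binomial(T, n_a / (n_a + n_b))`. The two-sided p-value sums, in the
#' spirit of Fisher's exact test, the probabilities of all splits no more
#' likely than the observed one (relative tie tolerance 1e-8).
#'
#' @param counts_a,counts_b Integer count vectors for the two groups (one gene,
#'   library-equalized samples).
#' @param phi Common dispersion, >= 0.
#' @return Two-sided p-value in `[0, 1]`; `T = 0` returns 1 by convention.
#' @export
nb_exact_test <- function(counts_a, counts_b, phi) {
  if (phi < 0) stop("phi must be >= 0")
  n_a <- length(counts_a); n_b <- length(counts_b)
  s_obs <- sum(counts_a)
  t_tot <- s_obs + sum(counts_b)
  if (t_tot == 0) return(1)
  s <- 0:t_tot
  if (phi == 0) {
    logw <- lchoose(t_tot, s) + s * log(n_a) + (t_tot - s) * log(n_b)
  } else {
    r_a <- n_a / phi; r_b <- n_b / phi
    logw <- lgamma(s + r_a) - lgamma(s + 1) + lgamma(t_tot - s + r_b) -
      lgamma(t_tot - s + 1)
  }
  logw <- logw - max(logw)
  w <- exp(logw)
  p <- sum(w[logw <= logw[s_obs + 1] + 1e-8]) / sum(w)
  min(1, max(0, p))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: with p-values sorted ascending, `q_i = min_{j >= i}
#' (p_j * m / j)`, mapped back to the input order (computed via
#' [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return FDR-adjusted values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Genome-wide negative-binomial exact-test differential expression
#'
#' Pairwise contrast of group B over group A: equalizes library sizes,
#' estimates one common dispersion by conditional maximum likelihood, applies
#' the negative-binomial exact test per gene, and adjusts p-values by
#' Benjamini-Hochberg. The log2 fold change uses the per-group means of the
#' equalized pseudo-counts with a small-count offset of `0.5 / n` per group,
#' `log2((mean_b + 0.5/n_b) / (mean_a + 0.5/n_a))`, so zero-count genes stay
#' finite. A gene is significant when `fdr < fdr_threshold` and
#' `|log2_fc| > logfc_threshold`.
#'
#' @param expr An [expression_matrix()] (raw integer counts; values are
#'   rounded defensively).
#' @param group_a,group_b Disjoint sample-id vectors, >= 2 samples each.
#' @param logfc_threshold Minimum `|log2FC|` for significance (default 0.58,
#'   i.e. a 50 percent expression change).
#' @param fdr_threshold FDR cutoff for significance (default 0.05).
#' @return Data frame of class `de_result`: `gene_id`, `log2_fc`, `p_value`,
#'   `fdr`, `mean_a`, `mean_b`, `significant`; the dispersion estimate is
#'   attached as attribute `"dispersion"`.
#' @export
differential_expression <- function(expr, group_a, group_b,
                                    logfc_threshold = 0.58,
                                    fdr_threshold = 0.05) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (length(intersect(group_a, group_b)))
    stop("groups overlap: ", paste(intersect(group_a, group_b), collapse = ", "))
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs >= 2 samples for dispersion estimation")
  missing <- setdiff(c(group_a, group_b), colnames(expr$counts))
  if (length(missing))
    stop("sample(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  counts <- round(expr$counts[, c(group_a, group_b), drop = FALSE])
  storage.mode(counts) <- "integer"
  eq <- equalize_library_sizes(counts)
  groups <- rep(c("A", "B"), c(length(group_a), length(group_b)))
  disp <- estimate_common_dispersion(eq$counts, groups)
  ya <- eq$counts[, groups == "A", drop = FALSE]
  yb <- eq$counts[, groups == "B", drop = FALSE]
  n_a <- ncol(ya); n_b <- ncol(yb)
  p <- vapply(seq_len(nrow(counts)), function(i)
    nb_exact_test(ya[i, ], yb[i, ], disp$phi), numeric(1))
  fdr <- bh_adjust(p)
  mean_a <- rowMeans(ya); mean_b <- rowMeans(yb)
  log2_fc <- log2((mean_b + 0.5 / n_b) / (mean_a + 0.5 / n_a))
  out <- data.frame(gene_id = rownames(counts), log2_fc = log2_fc,
                    p_value = p, fdr = fdr,
                    mean_a = mean_a, mean_b = mean_b,
                    significant = fdr < fdr_threshold & abs(log2_fc) > logfc_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "dispersion") <- disp
  class(out) <- c("de_result", "data.frame")
  out
}

#' @export
print.de_result <- function(x, n = 10, ...) {
  disp <- attr(x, "dispersion")
  cat(sprintf("de_result: %d genes, %d significant; phi = %.4f\n",
              nrow(x), sum(x$significant), disp$phi))
  print(utils::head(as.data.frame(x)[order(x$fdr), ], n))
  invisible(x)
}
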