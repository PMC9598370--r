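#' Expression matrix container
#'
#' Bundles a genes x samples count matrix with a per-sample condition label
#' (`"tumor"` or `"normal"`). Raw input counts are non-negative integers;
#' after normalization the values may be fractional but stay non-negative.
#'
#' @param counts Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are required, unique, and non-empty; gene identity is the
#'   official symbol string, case-sensitive.
#' @param condition Character vector of `"tumor"`/`"normal"`, either named by
#'   sample or in column order of `counts`.
#' @param integer_counts Require whole-number counts (used by the raw readers).
#' @return An object of class `expr_matrix`: a list with elements `counts`
#'   (the matrix) and `condition` (named character vector).
#' @examples
#' m <- matrix(c(3L, 0L, 1L, 5L), 2, dimnames = list(c("A", "B"), c("s1", "s2")))
#' expression_matrix(m, c(s1 = "tumor", s2 = "tumor"))
#' @export
expression_matrix <- function(counts, condition, integer_counts = FALSE) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix")
  gn <- rownames(counts); sn <- colnames(counts)
  if (is.null(gn) || is.null(sn) || any(!nzchar(gn)) || any(!nzchar(sn)))
    stop("'counts' needs non-empty row (gene) and column (sample) names")
  if (anyDuplicated(gn))
    stop("duplicate gene symbol(s): ", paste(unique(gn[duplicated(gn)]), collapse = ", "))
  if (anyDuplicated(sn))
    stop("duplicate sample id(s): ", paste(unique(sn[duplicated(sn)]), collapse = ", "))
  if (anyNA(counts)) stop("missing values are not permitted in the count matrix")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at gene '%s', sample '%s'", gn[bad[1]], sn[bad[2]]))
  }
  if (integer_counts && any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at gene '%s', sample '%s'", gn[bad[1]], sn[bad[2]]))
  }
  if (!is.null(names(condition))) {
    missing <- setdiff(sn, names(condition))
    if (length(missing))
      stop("sample(s) missing from condition table: ", paste(missing, collapse = ", "))
    condition <- condition[sn]
  } else {
    if (length(condition) != ncol(counts))
      stop("'condition' must have one entry per sample")
    names(condition) <- sn
  }
  condition <- as.character(condition); names(condition) <- sn
  if (!all(condition %in% c("tumor", "normal")))
    stop("condition labels must be 'tumor' or 'normal'")
  structure(list(counts = counts, condition = condition), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%d tumor, %d normal)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$condition == "tumor"), sum(x$condition == "normal")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$counts)

# subset an expr_matrix by gene / sample names or indices
subset_expr <- function(x, genes = NULL, samples = NULL) {
  counts <- x$counts
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  structure(list(counts = counts, condition = x$condition[colnames(counts)]),
            class = "expr_matrix")
}

#' Sample ids of one condition
#'
#' @param x An `expr_matrix`.
#' @param condition `"tumor"` or `"normal"`.
#' @return Character vector of sample ids.
#' @export
condition_samples <- function(x, condition = c("tumor", "normal")) {
  condition <- match.arg(condition)
  names(x$condition)[x$condition == condition]
}

#' Thresholded copy-number matrix container
#'
#' GISTIC-style discretized calls per gene and tumor sample: -2 homozygous
#' deletion, -1 hemizygous deletion, 0 diploid, +1 single-copy gain, +2
#' high-level amplification.
#'
#' @param calls Integer matrix in \{-2,...,+2\}, genes x samples, with unique
#'   non-empty dimnames.
#' @return An object of class `cn_matrix` wrapping the validated call matrix.
#' @export
copy_number_matrix <- function(calls) {
  if (!is.matrix(calls) || !is.numeric(calls))
    stop("'calls' must be a numeric matrix")
  gn <- rownames(calls); sn <- colnames(calls)
  if (is.null(gn) || is.null(sn)) stop("'calls' needs gene and sample names")
  if (anyDuplicated(gn))
    stop("duplicate gene symbol(s): ", paste(unique(gn[duplicated(gn)]), collapse = ", "))
  if (anyDuplicated(sn)) stop("duplicate sample id(s) in copy-number matrix")
  ok <- !is.na(calls) & calls %in% c(-2L, -1L, 0L, 1L, 2L)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("copy-number call outside {-2..+2} at gene '%s', sample '%s': %s",
                 gn[bad[1]], sn[bad[2]], calls[bad[1], bad[2]]))
  }
  storage.mode(calls) <- "integer"
  structure(list(calls = calls), class = "cn_matrix")
}

#' @export
print.cn_matrix <- function(x, ...) {
  cat(sprintf("cn_matrix: %d genes x %d samples; call distribution:\n",
              nrow(x$calls), ncol(x$calls)))
  print(table(x$calls))
  invisible(x)
}

#' Gene annotation table
#'
#' Per-gene genomic interval plus optional GC fraction and cancer-driver role.
#' Coordinates are held internally as 0-based half-open intervals.
#'
#' @param df Data frame with columns `gene_id`, `chrom`, `start`, `end` and
#'   optionally `gc_fraction` (in \[0,1\]) and `driver_role` (one of
#'   `"oncogene"`, `"tumor_suppressor"`, `"both"`, `"none"`).
#' @return A validated data frame of class `gene_annotation`.
#' @export
gene_annotation <- function(df) {
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(df)))
    stop("annotation needs columns: ", paste(need, collapse = ", "))
  df$gene_id <- as.character(df$gene_id)
  df$chrom <- as.character(df$chrom)
  if (anyDuplicated(df$gene_id))
    stop("duplicated gene_id in annotation: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  if (any(!nzchar(df$chrom)) || anyNA(df$chrom)) stop("empty chromosome label")
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (anyNA(df$start) || anyNA(df$end) || any(df$start >= df$end))
    stop("annotation requires start < end for every gene (0-based half-open)")
  if (is.null(df$gc_fraction)) df$gc_fraction <- NA_real_
  if (any(!is.na(df$gc_fraction) & (df$gc_fraction < 0 | df$gc_fraction > 1)))
    stop("gc_fraction must lie in [0, 1]")
  if (is.null(df$driver_role)) df$driver_role <- "none"
  df$driver_role[is.na(df$driver_role)] <- "none"
  ok_role <- c("oncogene", "tumor_suppressor", "both", "none")
  if (!all(df$driver_role %in% ok_role))
    stop("driver_role must be one of: ", paste(ok_role, collapse = ", "))
  df <- df[, c("gene_id", "chrom", "start", "end", "gc_fraction", "driver_role")]
  rownames(df) <- NULL
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' CRISPR dependency input tables
#'
#' Pairs a cell-line x gene Chronos score matrix (lower = stronger dependence)
#' with a cell-line x gene copy-number score matrix. The two tables are
#' intersected on both axes; missing values are permitted and dropped pairwise
#' downstream.
#'
#' @param chronos,cn_score Numeric matrices, cell lines in rows, genes in
#'   columns, with dimnames.
#' @return An object of class `dependency_input` with the two aligned matrices.
#' @export
dependency_input <- function(chronos, cn_score) {
  for (m in list(chronos, cn_score))
    if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m)))
      stop("dependency tables must be matrices with cell-line and gene names")
  lines <- intersect(rownames(chronos), rownames(cn_score))
  genes <- intersect(colnames(chronos), colnames(cn_score))
  if (!length(lines) || !length(genes))
    stop("chronos and copy-number tables share no cell lines or no genes")
  if (any(cn_score[lines, genes] < 0, na.rm = TRUE))
    stop("copy-number scores must be non-negative")
  structure(list(chronos = chronos[lines, genes, drop = FALSE],
                 cn_score = cn_score[lines, genes, drop = FALSE]),
            class = "dependency_input")
}

#' @export
print.dependency_input <- function(x, ...) {
  cat(sprintf("dependency_input: %d cell lines x %d genes\n",
              nrow(x$chronos), ncol(x$chronos)))
  invisible(x)
}
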