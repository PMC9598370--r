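#' Read a raw RNA-seq count matrix and its sample-condition table
#'
#' The count file is a TSV with gene symbols in the first column and one
#' column per sample. The condition file is a TSV with columns `sample_id`
#' and `condition` (`tumor`/`normal`); every sample in the count matrix must
#' appear in it.
#'
#' @param path Count matrix TSV.
#' @param condition_path Sample-condition TSV.
#' @return An [expression_matrix()] with validated integer counts.
#' @export
read_counts_matrix <- function(path, condition_path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("count matrix needs a gene column plus >= 1 sample column")
  genes <- as.character(raw[[1]])
  mat <- raw[, -1, drop = FALSE]
  for (j in seq_along(mat)) {
    v <- mat[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) | is.na(v))[1]
      stop(sprintf("non-numeric count at gene '%s', sample '%s'",
                   genes[if (length(bad)) bad else 1], names(mat)[j]))
    }
    if (anyNA(v)) {
      stop(sprintf("missing count at gene '%s', sample '%s'",
                   genes[which(is.na(v))[1]], names(mat)[j]))
    }
    if (any(v < 0)) {
      stop(sprintf("negative count at gene '%s', sample '%s'",
                   genes[which(v < 0)[1]], names(mat)[j]))
    }
  }
  m <- as.matrix(mat)
  rownames(m) <- genes
  cond <- utils::read.delim(condition_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(cond)))
    stop("condition table needs columns 'sample_id' and 'condition'")
  condition <- setNames(as.character(cond$condition), as.character(cond$sample_id))
  expression_matrix(m, condition, integer_counts = TRUE)
}

#' Read a GISTIC-style "thresholded by gene" copy-number matrix
#'
#' Expects a TSV whose leading metadata columns are recognized by header name
#' (`Gene Symbol` mandatory; `Locus ID` and `Cytoband` dropped when present),
#' followed by one column of integer calls in \{-2,...,+2\} per tumor sample.
#'
#' @param path TSV file path.
#' @return A [copy_number_matrix()].
#' @export
read_gistic_thresholded <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"Gene Symbol" %in% names(raw))
    stop("missing 'Gene Symbol' header: not a thresholded-by-gene file")
  meta <- intersect(c("Gene Symbol", "Locus ID", "Cytoband"), names(raw))
  genes <- as.character(raw[["Gene Symbol"]])
  calls <- as.matrix(raw[, setdiff(names(raw), meta), drop = FALSE])
  if (ncol(calls) == 0) stop("no sample columns after metadata columns")
  rownames(calls) <- genes
  copy_number_matrix(calls)
}

#' Read gene annotation (TSV or BED dialect)
#'
#' The BED dialect is headerless, 0-based half-open:
#' `chrom start end gene_id [gc_fraction] [driver_role]`. The TSV dialect has
#' a header (`gene_id chrom start end [gc_fraction] [driver_role]`) and
#' declares 1-based inclusive coordinates, converted to the internal 0-based
#' half-open convention on read.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"bed"`.
#' @return A [gene_annotation()] data frame (0-based half-open coordinates).
#' @export
read_gene_annotation <- function(path, dialect = c("tsv", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(raw) < 4) stop("BED annotation needs >= 4 columns")
    names(raw)[1:4] <- c("chrom", "start", "end", "gene_id")
    if (ncol(raw) >= 5) names(raw)[5] <- "gc_fraction"
    if (ncol(raw) >= 6) names(raw)[6] <- "driver_role"
    df <- raw
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "chrom", "start", "end") %in% names(df)))
      stop("TSV annotation needs columns gene_id, chrom, start, end")
    df$start <- df$start - 1  # 1-based inclusive -> 0-based half-open
  }
  gene_annotation(df)
}

#' Read a cancer-driver census gene list
#'
#' CSV with a gene-symbol column (`gene_id`, `gene` or `Gene Symbol`) and a
#' role column (`driver_role`, `role` or `Role in Cancer`). Role strings are
#' normalized to `oncogene`, `tumor_suppressor` or `both`; a label naming both
#' activities maps to `both`, an unrecognized label maps to `both` with a
#' warning.
#'
#' @param path CSV file path.
#' @return Data frame with columns `gene_id` and `driver_role` (possibly
#'   zero rows).
#' @export
read_driver_census <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0)
    return(data.frame(gene_id = character(), driver_role = character(),
                      stringsAsFactors = FALSE))
  gene_col <- intersect(c("gene_id", "gene", "Gene Symbol"), names(raw))[1]
  role_col <- intersect(c("driver_role", "role", "Role in Cancer"), names(raw))[1]
  if (is.na(gene_col) || is.na(role_col))
    stop("driver census needs a gene-symbol column and a role column")
  roles <- vapply(as.character(raw[[role_col]]), normalize_driver_role, character(1))
  out <- data.frame(gene_id = as.character(raw[[gene_col]]),
                    driver_role = unname(roles), stringsAsFactors = FALSE)
  out[!duplicated(out$gene_id), , drop = FALSE]
}

normalize_driver_role <- function(role) {
  r <- tolower(role)
  onc <- grepl("onco", r)
  tsg <- grepl("tsg|suppressor", r)
  if (onc && tsg) return("both")
  if (grepl("^both$", trimws(r))) return("both")
  if (onc) return("oncogene")
  if (tsg) return("tumor_suppressor")
  warning(sprintf("unrecognized driver role '%s'; recording as 'both'", role))
  "both"
}

#' Read DepMap-like dependency tables
#'
#' Two CSVs with cell lines in rows (first column `cell_line`) and genes in
#' columns: Chronos dependency scores and copy-number scores. Missing values
#' are permitted and dropped pairwise downstream.
#'
#' @param chronos_path,cn_score_path CSV file paths.
#' @return A [dependency_input()].
#' @export
read_dependency_input <- function(chronos_path, cn_score_path) {
  read_one <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    storage.mode(m) <- "double"
    m
  }
  dependency_input(read_one(chronos_path), read_one(cn_score_path))
}

# ---- canonical output tables ----------------------------------------------

record_columns <- function() {
  c(gene_id = "character", event_type = "character", recurrence = "numeric",
    n_altered = "integer", altered_sample_ids = "character",
    log2_fc_sd = "numeric", p_sd = "numeric", fdr_sd = "numeric",
    log2_fc_tn = "numeric", fdr_tn = "numeric",
    subset = "character", subclass = "character",
    subgroup = "character", rank = "integer")
}

#' Empty SCNV-DEG record table
#'
#' @return Zero-row data frame with the canonical record columns.
#' @export
empty_records <- function() {
  cols <- record_columns()
  out <- lapply(cols, function(cl) vector(cl, 0))
  structure(as.data.frame(out, stringsAsFactors = FALSE), names = names(cols))
}

pair_columns <- function() {
  c(gene_a = "character", gene_b = "character", event_type = "character",
    n_both = "integer", n_a_only = "integer", n_b_only = "integer",
    n_neither = "integer", odds_ratio = "numeric", p_value = "numeric",
    fdr = "numeric", relation = "character")
}

empty_pairs <- function() {
  cols <- pair_columns()
  structure(as.data.frame(lapply(cols, function(cl) vector(cl, 0)),
                          stringsAsFactors = FALSE), names = names(cols))
}

window_columns <- function() {
  c(chrom = "character", start = "numeric", end = "numeric",
    count = "integer", candidate = "logical", enriched = "logical")
}

dependency_columns <- function() {
  c(gene_id = "character", n_amplified = "integer", n_diploid = "integer",
    median_amplified = "numeric", median_diploid = "numeric",
    median_diff = "numeric", p_value = "numeric", significant = "logical",
    reason = "character")
}

write_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.numeric(df2[[j]]) && !is.integer(df2[[j]]))
      df2[[j]] <- vapply(df2[[j]], function(v)
        if (is.na(v)) NA_character_ else format(v, digits = 17, trim = TRUE),
        character(1))
  }
  utils::write.table(df2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", na = "NA")
}

read_typed_tsv <- function(path, cols) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = unname(cols), check.names = FALSE)
  names(df) <- names(cols)
  df
}

#' Read back pipeline output tables
#'
#' Re-reads the TSVs written by [write_results()] with their canonical column
#' types, so that a write-then-read round trip reproduces the tables.
#'
#' @param path TSV file path.
#' @return Data frame with the table's canonical columns.
#' @export
read_scnv_deg_table <- function(path) read_typed_tsv(path, record_columns())

#' @rdname read_scnv_deg_table
#' @export
read_cooccurrence_table <- function(path) read_typed_tsv(path, pair_columns())

#' @rdname read_scnv_deg_table
#' @export
read_windows_table <- function(path) read_typed_tsv(path, window_columns())

#' @rdname read_scnv_deg_table
#' @export
read_dependency_table <- function(path) read_typed_tsv(path, dependency_columns())

#' Write the full result set of a pipeline run
#'
#' Emits, in deterministic column and row order: `scnv_deg.tsv` (one row per
#' SCNV-DEG record), `cooccurrence.tsv`, `windows.tsv`, `dependency.tsv`, the
#' static scatter export `scatter.tsv` (x = tumor-vs-normal log2FC, y =
#' SCNV-vs-diploid log2FC, size = recurrence) and a JSON run summary holding
#' parameters, per-subset/subclass counts and the seed. Two runs with an
#' identical configuration and seed produce byte-identical files.
#'
#' @param records SCNV-DEG record data frame (see [empty_records()]).
#' @param pairs Co-occurrence pair data frame.
#' @param windows Genomic window data frame.
#' @param dep Dependency result data frame (or `NULL`).
#' @param out_dir Output directory, created if needed.
#' @param summary Named list stored as `run_summary.json` (parameters, seed,
#'   ...); subset/subclass counts are appended automatically.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_results <- function(records, pairs, windows, dep = NULL, out_dir,
                          summary = list()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(records) || nrow(records) == 0) records <- empty_records()
  if (is.null(pairs) || nrow(pairs) == 0) pairs <- empty_pairs()
  if (is.null(windows)) {
    cols <- window_columns()
    windows <- structure(as.data.frame(lapply(cols, function(cl) vector(cl, 0)),
                                       stringsAsFactors = FALSE),
                         names = names(cols))
  }
  if (is.null(dep)) {
    cols <- dependency_columns()
    dep <- structure(as.data.frame(lapply(cols, function(cl) vector(cl, 0)),
                                   stringsAsFactors = FALSE),
                     names = names(cols))
  }
  paths <- c(scnv_deg = file.path(out_dir, "scnv_deg.tsv"),
             cooccurrence = file.path(out_dir, "cooccurrence.tsv"),
             windows = file.path(out_dir, "windows.tsv"),
             dependency = file.path(out_dir, "dependency.tsv"),
             scatter = file.path(out_dir, "scatter.tsv"),
             summary = file.path(out_dir, "run_summary.json"))
  write_tsv(records[, names(record_columns())], paths["scnv_deg"])
  write_tsv(pairs[, names(pair_columns())], paths["cooccurrence"])
  write_tsv(windows[, names(window_columns())], paths["windows"])
  write_tsv(dep[, names(dependency_columns())], paths["dependency"])
  scatter <- records[, c("gene_id", "event_type", "log2_fc_tn", "log2_fc_sd",
                         "recurrence", "subset")]
  write_tsv(scatter, paths["scatter"])
  summary$n_records <- nrow(records)
  summary$subset_counts <- as.list(table(factor(records$subset,
    levels = c("a.1", "a.2", "b.1", "b.2", "c.1", "c.2", "no_normal"))))
  summary$subclass_counts <- as.list(table(factor(records$subclass,
    levels = c("i", "ii_a", "ii_b", "iii"))))
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(paths)
}
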