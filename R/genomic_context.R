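#' Binary alteration matrix for one direction
#'
#' Encodes the thresholded calls in binary notation: 1 when the call is
#' altered for the given direction/mode, 0 otherwise (diploid and excluded
#' calls both map to 0).
#'
#' @param cn A [copy_number_matrix()].
#' @inheritParams classify_cn_status
#' @return Integer 0/1 matrix with the same dimnames as the call matrix.
#' @export
binarize_events <- function(cn, direction = "amplification", mode = "deep") {
  stopifnot(inherits(cn, "cn_matrix"))
  status <- classify_cn_status(as.vector(cn$calls), mode, direction)
  out <- matrix(as.integer(status == "altered"), nrow = nrow(cn$calls),
                dimnames = dimnames(cn$calls))
  out
}

#' Fisher co-occurrence test for two binary alteration profiles
#'
#' Builds the 2x2 table (both, a only, b only, neither) over samples and
#' computes the two-sided Fisher exact p-value from the hypergeometric law.
#' The reported odds ratio is the sample odds ratio, Haldane-corrected
#' (+0.5 in every cell) only when a zero cell exists; the pair is
#' `co_occurring` when that odds ratio exceeds 1, `mutually_exclusive`
#' otherwise.
#'
#' @param vec_a,vec_b Binary 0/1 vectors of equal length >= 1.
#' @return List: `table` (named counts), `odds_ratio`, `p_value`, `relation`.
#' @export
cooccurrence_test <- function(vec_a, vec_b) {
  if (length(vec_a) != length(vec_b) || length(vec_a) < 1)
    stop("binary vectors must have equal length >= 1")
  a <- vec_a != 0; b <- vec_b != 0
  n_both <- sum(a & b); n_a <- sum(a & !b); n_b <- sum(!a & b)
  n_neither <- sum(!a & !b)
  tab <- matrix(c(n_both, n_a, n_b, n_neither), nrow = 2)
  p <- stats::fisher.test(tab)$p.value
  cells <- c(n_both, n_a, n_b, n_neither)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  list(table = c(both = n_both, a_only = n_a, b_only = n_b, neither = n_neither),
       odds_ratio = or, p_value = p,
       relation = if (or > 1) "co_occurring" else "mutually_exclusive")
}

#' Driver-anchored co-occurrence scan over SCNV-DEG pairs
#'
#' Tests every pair of SCNV-DEG records of the same event type in which at
#' least one member is a census driver, and keeps pairs with Fisher
#' `p < alpha`. No multiplicity correction is applied to the retention rule;
#' a Benjamini-Hochberg column over all tested pairs is emitted alongside for
#' the user.
#'
#' @param records SCNV-DEG record data frame.
#' @param cn A [copy_number_matrix()] restricted to the tumor samples used in
#'   the scan.
#' @param drivers Census data frame (`gene_id`, `driver_role`) from
#'   [read_driver_census()].
#' @param mode Copy-number mode used for binarization (default `"deep"`).
#' @param alpha Retention threshold on the uncorrected p-value (default 0.05).
#' @return Co-occurrence pair data frame (possibly zero rows).
#' @export
driver_cooccurrence_scan <- function(records, cn, drivers, mode = "deep",
                                     alpha = 0.05) {
  if (is.null(drivers) || nrow(drivers) == 0) {
    warning("empty driver census: co-occurrence scan returns no pairs and ",
            "driver-dependent outputs are downgraded")
    return(empty_pairs())
  }
  if (nrow(records) == 0) return(empty_pairs())
  rows <- list()
  for (direction in unique(records$event_type)) {
    genes <- records$gene_id[records$event_type == direction]
    genes <- intersect(genes, rownames(cn$calls))
    if (length(genes) < 2) next
    bin <- binarize_events(cn, direction = direction, mode = mode)[genes, , drop = FALSE]
    is_driver <- genes %in% drivers$gene_id
    combs <- utils::combn(seq_along(genes), 2)
    for (k in seq_len(ncol(combs))) {
      i <- combs[1, k]; j <- combs[2, k]
      if (!is_driver[i] && !is_driver[j]) next
      ct <- cooccurrence_test(bin[i, ], bin[j, ])
      rows[[length(rows) + 1]] <- data.frame(
        gene_a = genes[i], gene_b = genes[j], event_type = direction,
        n_both = unname(ct$table["both"]), n_a_only = unname(ct$table["a_only"]),
        n_b_only = unname(ct$table["b_only"]), n_neither = unname(ct$table["neither"]),
        odds_ratio = ct$odds_ratio, p_value = ct$p_value, fdr = NA_real_,
        relation = ct$relation, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_pairs())
  pairs <- do.call(rbind, rows)
  pairs$fdr <- bh_adjust(pairs$p_value)
  pairs <- pairs[pairs$p_value < alpha, , drop = FALSE]
  pairs <- pairs[order(pairs$event_type, pairs$gene_a, pairs$gene_b), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Tile the genome into fixed-size windows
#'
#' Per chromosome, windows `[k*w, (k+1)*w)` from 0 up to the maximal annotated
#' gene end; the tail window is clipped to that end. Counts are unfilled
#' (zero) until [enriched_windows()] assigns records.
#'
#' @param annotation A [gene_annotation()].
#' @param window_size Window width in bp (default 1e7, i.e. 10 Mb).
#' @return Window data frame: `chrom`, `start`, `end`, `count`, `candidate`,
#'   `enriched`.
#' @export
tile_genome <- function(annotation, window_size = 1e7) {
  if (nrow(annotation) == 0) stop("empty annotation")
  rows <- lapply(split(annotation, annotation$chrom), function(a) {
    max_end <- max(a$end)
    k <- seq_len(ceiling(max_end / window_size)) - 1
    data.frame(chrom = a$chrom[1], start = k * window_size,
               end = pmin((k + 1) * window_size, max_end),
               count = 0L, candidate = FALSE, enriched = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# window index (row of `windows`) containing each gene's interval midpoint;
# NA when the gene is not annotated
assign_windows <- function(gene_ids, windows, annotation) {
  idx <- match(gene_ids, annotation$gene_id)
  mid <- floor((annotation$start[idx] + annotation$end[idx]) / 2)
  chrom <- annotation$chrom[idx]
  vapply(seq_along(gene_ids), function(i) {
    if (is.na(idx[i])) return(NA_integer_)
    w <- which(windows$chrom == chrom[i] & windows$start <= mid[i] &
                 mid[i] < windows$end)
    if (length(w)) w[1] else NA_integer_
  }, integer(1))
}

#' Flag SCNV-DEG-enriched genomic windows
#'
#' Assigns each record to the window containing its gene-interval midpoint,
#' then applies the enrichment rule: candidate windows hold more than two
#' SCNV-DEGs; among candidates the mean count is computed, and a window is
#' enriched when its count strictly exceeds that mean. When all candidates
#' tie, none is enriched.
#'
#' @param windows Output of [tile_genome()].
#' @param records SCNV-DEG record data frame.
#' @param annotation A [gene_annotation()].
#' @return The window data frame with `count`, `candidate` and `enriched`
#'   filled; the per-record window index is attached as attribute
#'   `"record_window"`.
#' @export
enriched_windows <- function(windows, records, annotation) {
  wi <- assign_windows(records$gene_id, windows, annotation)
  counts <- tabulate(wi, nbins = nrow(windows))
  windows$count <- as.integer(counts)
  windows$candidate <- windows$count > 2L
  if (any(windows$candidate)) {
    avg <- mean(windows$count[windows$candidate])
    windows$enriched <- windows$candidate & windows$count > avg
  } else {
    windows$enriched <- FALSE
  }
  attr(windows, "record_window") <- wi
  windows
}

#' Genomic-context subclass of one SCNV-DEG record
#'
#' Precedence: (i) the gene itself is a census driver; else (ii_b) it has a
#' significant co-occurrence with a driver SCNV-DEG on a different chromosome
#' (trans linkage, putative driver); else (iii) its midpoint shares an
#' enriched window with a driver SCNV-DEG, or it co-occurs significantly with
#' a driver SCNV-DEG on the same chromosome (cis linkage, uncertain
#' relevance); else (ii_a) no driver linkage at all (putative driver,
#' driver-independent).
#'
#' @param gene_id Record gene symbol.
#' @param pairs Significant co-occurrence pairs (from
#'   [driver_cooccurrence_scan()]).
#' @param windows Enriched-window table from [enriched_windows()].
#' @param records All SCNV-DEG records (to locate driver records in windows).
#' @param annotation A [gene_annotation()].
#' @param drivers Census data frame.
#' @return One of `"i"`, `"ii_a"`, `"ii_b"`, `"iii"`.
#' @export
catalog_subclass <- function(gene_id, pairs, windows, records, annotation,
                             drivers) {
  driver_set <- if (is.null(drivers)) character() else drivers$gene_id
  if (gene_id %in% driver_set) return("i")
  chrom_of <- function(g) annotation$chrom[match(g, annotation$gene_id)]
  partners <- character()
  if (nrow(pairs)) {
    hit <- pairs$gene_a == gene_id | pairs$gene_b == gene_id
    partner <- ifelse(pairs$gene_a[hit] == gene_id, pairs$gene_b[hit],
                      pairs$gene_a[hit])
    partners <- partner[partner %in% driver_set]
  }
  if (length(partners)) {
    same <- chrom_of(partners) == chrom_of(gene_id)
    if (any(!same, na.rm = TRUE)) return("ii_b")
  }
  wi <- assign_windows(gene_id, windows, annotation)
  in_enriched_with_driver <- FALSE
  if (!is.na(wi) && windows$enriched[wi]) {
    driver_records <- records$gene_id[records$gene_id %in% driver_set]
    if (length(driver_records)) {
      dwi <- assign_windows(driver_records, windows, annotation)
      in_enriched_with_driver <- any(dwi == wi, na.rm = TRUE)
    }
  }
  cis_cooccurrence <- length(partners) > 0  # remaining partners are same-chromosome
  if (in_enriched_with_driver || cis_cooccurrence) return("iii")
  "ii_a"
}

#' Stratify SCNV-DEG records and rank within subgroups
#'
#' Splits records 2x2 by driver co-occurrence (a significant pair with a
#' census-driver partner) and enriched-window membership, then ranks within
#' each subgroup by SCNV recurrence (descending), breaking ties by the
#' SCNV-versus-diploid FDR (ascending) and then by gene symbol for
#' determinism. Also fills the `subclass` column via [catalog_subclass()].
#'
#' @param records SCNV-DEG record data frame.
#' @param pairs Significant co-occurrence pairs.
#' @param windows Enriched-window table from [enriched_windows()].
#' @param annotation A [gene_annotation()].
#' @param drivers Census data frame.
#' @return The records with `subclass`, `subgroup` and `rank` filled, ordered
#'   by subgroup then rank.
#' @export
stratify_and_rank <- function(records, pairs, windows, annotation, drivers) {
  if (nrow(records) == 0) return(records)
  driver_set <- if (is.null(drivers)) character() else drivers$gene_id
  cooc <- vapply(records$gene_id, function(g) {
    if (!nrow(pairs)) return(FALSE)
    hit <- pairs$gene_a == g | pairs$gene_b == g
    partner <- ifelse(pairs$gene_a[hit] == g, pairs$gene_b[hit], pairs$gene_a[hit])
    any(partner %in% driver_set)
  }, logical(1))
  wi <- assign_windows(records$gene_id, windows, annotation)
  in_enriched <- !is.na(wi) & windows$enriched[ifelse(is.na(wi), 1L, wi)]
  records$subgroup <- paste0(ifelse(cooc, "driver_cooc", "no_driver_cooc"), "/",
                             ifelse(in_enriched, "enriched", "not_enriched"))
  records$subclass <- vapply(records$gene_id, catalog_subclass, character(1),
                             pairs = pairs, windows = windows, records = records,
                             annotation = annotation, drivers = drivers)
  records$rank <- NA_integer_
  for (sg in unique(records$subgroup)) {
    idx <- which(records$subgroup == sg)
    ord <- order(-records$recurrence[idx], records$fdr_sd[idx],
                 records$gene_id[idx])
    records$rank[idx[ord]] <- seq_along(idx)
  }
  records <- records[order(records$subgroup, records$rank), , drop = FALSE]
  rownames(records) <- NULL
  records
}
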