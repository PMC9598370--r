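#' Classify a thresholded copy-number call for one contrast
#'
#' Under `deep` mode only high-level events count as altered (+2 for
#' amplification, -2 for deletion); under `shallow` only single-copy events
#' (+1 / -1); `combined` pools both. A call of 0 is diploid, anything else is
#' excluded from the contrast (e.g. +1 under deep amplification, or any
#' deletion call when testing amplification).
#'
#' @param call Integer call(s) in \{-2,...,+2\} (vectorized).
#' @param mode `"deep"`, `"shallow"` or `"combined"`.
#' @param direction `"amplification"` or `"deletion"`.
#' @return Character vector in \{"altered", "diploid", "excluded"\}.
#' @export
classify_cn_status <- function(call, mode = c("deep", "shallow", "combined"),
                               direction = c("amplification", "deletion")) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  sgn <- if (direction == "amplification") 1L else -1L
  altered <- switch(mode,
    deep = call == 2L * sgn,
    shallow = call == 1L * sgn,
    combined = call * sgn >= 1L)
  out <- rep("excluded", length(call))
  out[altered] <- "altered"
  out[call == 0L] <- "diploid"
  out
}

#' SCNV recurrence of a gene
#'
#' Fraction of tumor samples in the copy-number matrix carrying the alteration
#' (excluded samples stay in the denominator).
#'
#' @param cn A [copy_number_matrix()].
#' @param gene Gene symbol present in `cn`.
#' @inheritParams classify_cn_status
#' @return List with `recurrence`, `n_altered`, `altered_samples` and
#'   `diploid_samples`.
#' @export
compute_recurrence <- function(cn, gene, mode = "deep", direction = "amplification") {
  stopifnot(inherits(cn, "cn_matrix"))
  if (!gene %in% rownames(cn$calls)) stop("gene absent from copy-number matrix: ", gene)
  status <- classify_cn_status(cn$calls[gene, ], mode, direction)
  samples <- colnames(cn$calls)
  list(recurrence = sum(status == "altered") / length(status),
       n_altered = sum(status == "altered"),
       altered_samples = samples[status == "altered"],
       diploid_samples = samples[status == "diploid"])
}

#' Tumor-versus-normal differential expression contrast
#'
#' Runs the genome-wide negative-binomial exact-test contrast of tumor over
#' normal samples. Under the `all_tumors` policy every tumor sample enters one
#' shared contrast (computed once per run); under `diploid_only` the contrast
#' is recomputed per queried gene using only that gene's diploid tumors.
#'
#' @param expr An [expression_matrix()] containing >= 2 normal samples.
#' @param tumor_samples Optional subset of tumor sample ids (used by the
#'   `diploid_only` policy); defaults to all tumors.
#' @param logfc_threshold,fdr_threshold Significance thresholds.
#' @return A `de_result` (group A = normal, group B = tumor), or `NULL` when
#'   fewer than 2 normal samples exist (callers then label subsets
#'   `no_normal`).
#' @export
tumor_normal_contrast <- function(expr, tumor_samples = NULL,
                                  logfc_threshold = 0.58, fdr_threshold = 0.05) {
  normals <- condition_samples(expr, "normal")
  if (length(normals) < 2) return(NULL)
  if (is.null(tumor_samples)) tumor_samples <- condition_samples(expr, "tumor")
  if (length(tumor_samples) < 2) return(NULL)
  differential_expression(expr, group_a = normals, group_b = tumor_samples,
                          logfc_threshold = logfc_threshold,
                          fdr_threshold = fdr_threshold)
}

#' Expression-subset label from the two contrasts' significance pattern
#'
#' Maps the direction of the significant SCNV-versus-diploid change
#' (`sig_sd`, `"up"`/`"down"`) and the tumor-versus-normal status (`sig_tn`,
#' `"up"`/`"down"`/`"none"`) to the six expression subsets: `a.*` =
#' SCNV-only change, `b.*` = same-direction reinforcement of the
#' tumor-versus-normal change, `c.*` = direction reversal (`.1` up in SCNV,
#' `.2` down in SCNV).
#'
#' @param sig_sd `"up"` or `"down"` (vectorized).
#' @param sig_tn `"up"`, `"down"` or `"none"` (vectorized).
#' @return Subset labels in \{"a.1","a.2","b.1","b.2","c.1","c.2"\}.
#' @export
classify_subset <- function(sig_sd, sig_tn) {
  key <- paste(sig_sd, sig_tn, sep = "|")
  map <- c("up|none" = "a.1", "down|none" = "a.2",
           "up|up" = "b.1", "down|down" = "b.2",
           "up|down" = "c.1", "down|up" = "c.2")
  out <- unname(map[key])
  if (anyNA(out)) stop("invalid (sig_sd, sig_tn) combination: ",
                       paste(key[is.na(out)], collapse = ", "))
  out
}

#' Scan queried genes for SCNV-linked differential expression
#'
#' For every queried gene and direction (amplification and deletion are tested
#' independently), tumor samples are split into altered and diploid groups by
#' that gene's thresholded calls; when both groups reach `min_altered` /
#' `min_diploid` samples a genome-wide differential-expression contrast of
#' altered over diploid is run, and a record is emitted iff the queried gene
#' itself is significant in that contrast. FDR is computed over all genes of
#' the contrast when `fdr_scope = "genome"`, or over the queried genes' own
#' p-values when `fdr_scope = "queried"`.
#'
#' @param expr An [expression_matrix()] of raw tumor counts (post filtering);
#'   the exact test consumes library-equalized integer counts.
#' @param cn A [copy_number_matrix()] sharing tumor samples with `expr`.
#' @param queried Gene symbols to interrogate (default: all genes present in
#'   both matrices).
#' @param mode Copy-number mode, see [classify_cn_status()] (default
#'   `"deep"`).
#' @param min_altered Minimum altered and diploid group size (default 3).
#' @param logfc_threshold,fdr_threshold Significance thresholds (defaults
#'   0.58 / 0.05).
#' @param fdr_scope `"genome"` (default) or `"queried"`.
#' @param tn A `de_result` from [tumor_normal_contrast()] (or `NULL` when no
#'   normals are available; subsets are then `no_normal`).
#' @return List with `records` (canonical SCNV-DEG record data frame, ranked
#'   later by [stratify_and_rank()]) and `skipped` (gene/direction/reason).
#' @export
scnv_deg_scan <- function(expr, cn, queried = NULL,
                          mode = c("deep", "shallow", "combined"),
                          min_altered = 3,
                          logfc_threshold = 0.58, fdr_threshold = 0.05,
                          fdr_scope = c("genome", "queried"),
                          tn = NULL) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(cn, "cn_matrix"))
  mode <- match.arg(mode)
  fdr_scope <- match.arg(fdr_scope)
  tumors <- condition_samples(expr, "tumor")
  shared <- intersect(tumors, colnames(cn$calls))
  if (!length(shared))
    stop("expression and copy-number matrices share no tumor samples")
  genes_both <- intersect(rownames(expr$counts), rownames(cn$calls))
  if (is.null(queried)) queried <- genes_both
  absent <- setdiff(queried, genes_both)
  queried <- intersect(queried, genes_both)

  skipped <- list()
  for (g in absent)
    skipped[[length(skipped) + 1]] <- data.frame(
      gene_id = g, direction = "both", reason = "absent_from_inputs",
      stringsAsFactors = FALSE)

  rows <- list()
  contrasts <- list()  # per (gene, direction): de row + groups
  for (g in queried) {
    for (direction in c("amplification", "deletion")) {
      status <- classify_cn_status(cn$calls[g, shared], mode, direction)
      altered <- shared[status == "altered"]
      diploid <- shared[status == "diploid"]
      if (length(altered) < min_altered || length(diploid) < min_altered) {
        if (any(cn$calls[g, shared] != 0L))
          skipped[[length(skipped) + 1]] <- data.frame(
            gene_id = g, direction = direction,
            reason = sprintf("group_too_small (altered=%d, diploid=%d, min=%d)",
                             length(altered), length(diploid), min_altered),
            stringsAsFactors = FALSE)
        next
      }
      de <- differential_expression(expr, group_a = diploid, group_b = altered,
                                    logfc_threshold = logfc_threshold,
                                    fdr_threshold = fdr_threshold)
      row <- de[de$gene_id == g, ]
      fdr_g <- if (fdr_scope == "genome") row$fdr else row$p_value  # re-adjusted below
      contrasts[[paste(g, direction)]] <- list(
        gene_id = g, direction = direction, row = row, fdr = fdr_g,
        altered = altered, n_tumor = length(shared))
    }
  }
  if (fdr_scope == "queried" && length(contrasts)) {
    ps <- vapply(contrasts, function(x) x$fdr, numeric(1))
    qs <- bh_adjust(ps)
    for (i in seq_along(contrasts)) contrasts[[i]]$fdr <- qs[i]
  }
  for (cx in contrasts) {
    row <- cx$row
    if (!(cx$fdr < fdr_threshold && abs(row$log2_fc) > logfc_threshold)) next
    sig_sd <- if (row$log2_fc > 0) "up" else "down"
    if (is.null(tn)) {
      log2_fc_tn <- NA_real_; fdr_tn <- NA_real_; subset <- "no_normal"
    } else {
      tn_row <- tn[tn$gene_id == cx$gene_id, ]
      if (nrow(tn_row) == 0) {
        log2_fc_tn <- NA_real_; fdr_tn <- NA_real_; subset <- "no_normal"
      } else {
        log2_fc_tn <- tn_row$log2_fc; fdr_tn <- tn_row$fdr
        sig_tn <- if (!tn_row$significant) "none"
                  else if (tn_row$log2_fc > 0) "up" else "down"
        subset <- classify_subset(sig_sd, sig_tn)
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = cx$gene_id, event_type = cx$direction,
      recurrence = length(cx$altered) / cx$n_tumor,
      n_altered = length(cx$altered),
      altered_sample_ids = paste(sort(cx$altered), collapse = ","),
      log2_fc_sd = row$log2_fc, p_sd = row$p_value, fdr_sd = cx$fdr,
      log2_fc_tn = log2_fc_tn, fdr_tn = fdr_tn,
      subset = subset, subclass = NA_character_,
      subgroup = NA_character_, rank = NA_integer_,
      stringsAsFactors = FALSE)
  }
  records <- if (length(rows)) do.call(rbind, rows) else empty_records()
  records <- records[order(records$gene_id, records$event_type), , drop = FALSE]
  rownames(records) <- NULL
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(gene_id = character(), direction = character(),
               reason = character(), stringsAsFactors = FALSE)
  list(records = records, skipped = skipped)
}
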