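# annotation/record fixture whose genes produce the given per-window counts
# on a single chromosome (plus an uncounted anchor gene fixing the tiling span)
window_fixture <- function(counts, w = 1e7) {
  genes <- list()
  for (i in seq_along(counts)) {
    k <- counts[i]
    if (k == 0) next
    for (j in seq_len(k)) {
      mid <- (i - 1) * w + j * 1e5
      genes[[length(genes) + 1]] <- data.frame(
        gene_id = sprintf("w%d_g%d", i, j), chrom = "chr1",
        start = mid - 100, end = mid + 100, stringsAsFactors = FALSE)
    }
  }
  genes[[length(genes) + 1]] <- data.frame(
    gene_id = "anchor", chrom = "chr1",
    start = length(counts) * w - 200, end = length(counts) * w - 1,
    stringsAsFactors = FALSE)
  ann <- gene_annotation(do.call(rbind, genes))
  rec <- empty_records()
  for (g in setdiff(ann$gene_id, "anchor"))
    rec[nrow(rec) + 1, c("gene_id", "event_type", "recurrence", "fdr_sd")] <-
      list(g, "amplification", 0.2, 1e-3)
  list(ann = ann, rec = rec)
}
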