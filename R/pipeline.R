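default_config <- function() {
  list(
    # preprocessing (each step individually skippable)
    outlier_removal = TRUE, cor_cut = 0.6,
    low_expr_filter = TRUE, low_expr_quartile = 0.25,
    within_lane = "gc",          # gc | length | off
    within_lane_bins = 10,
    between_lane = "full_quantile",  # full_quantile | upper_quartile | off
    # differential expression
    logfc_threshold = 0.58, fdr_threshold = 0.05,
    # copy-number integration
    cn_mode = "deep", min_altered = 3, fdr_scope = "genome",
    tn_policy = "all_tumors",    # all_tumors | diploid_only
    # genomic context
    cooccur_alpha = 0.05, window_size = 1e7,
    # dependency screen
    dep_amp_cutoff = 2.5, dep_dip_low = 1.5, dep_median_diff = 0.10,
    dep_alpha = 0.05, dep_min_group = 5,
    # queried genes: NULL means every gene present in both matrices
    queried = NULL)
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML file path or a named list")
  cfg <- default_config()
  unknown <- setdiff(names(config), c(names(cfg), "counts", "conditions",
                                      "gistic", "annotation", "annotation_dialect",
                                      "drivers", "dep_chronos", "dep_cn_score"))
  if (length(unknown))
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in intersect(names(config), names(cfg))) cfg[[k]] <- config[[k]]
  for (k in c("counts", "conditions", "gistic", "annotation",
              "annotation_dialect", "drivers", "dep_chronos", "dep_cn_score"))
    cfg[[k]] <- config[[k]]
  cfg
}

#' Run the full SCNV-DEG discovery pipeline
#'
#' Executes, on files named in the configuration or on in-memory objects:
#' preprocessing (outlier removal, low-expression filtering, within- and
#' between-lane normalization for reporting), the tumor-versus-normal
#' contrast, the per-gene SCNV-versus-diploid scan, genomic-context
#' annotation (driver co-occurrence, enriched 10-Mb windows, subclassing,
#' stratified ranking), the optional CRISPR dependency screen, and the result
#' writer. Every parameter, default substitution, skipped step and the seed
#' are recorded in the JSON run summary; two runs with the same configuration
#' and seed produce byte-identical outputs, regardless of `threads`.
#'
#' @param config YAML file path or named list. Input keys: `counts`,
#'   `conditions`, `gistic`, `annotation` (+ `annotation_dialect`), `drivers`,
#'   and optionally `dep_chronos` / `dep_cn_score`; parameter keys default to
#'   the documented values (see the package vignette). Alternatively pass
#'   in-memory objects via `expr`, `cn`, `annotation`, `drivers`, `dep`.
#' @param out_dir Output directory for [write_results()].
#' @param seed Integer seed recorded in the summary (the analysis itself is
#'   deterministic; the seed also fixes any future stochastic extension).
#' @param threads Accepted for interface compatibility; per-gene contrasts
#'   are independent and are evaluated sequentially, so results do not depend
#'   on this value.
#' @param expr,cn,annotation,drivers,dep Optional in-memory inputs overriding
#'   the file paths in `config`.
#' @return Invisibly, an object of class `scnvdeg_run`: list with `records`,
#'   `pairs`, `windows`, `dependency`, `skipped`, `summary` and `paths`.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1, threads = 1,
                         expr = NULL, cn = NULL, annotation = NULL,
                         drivers = NULL, dep = NULL) {
  cfg <- read_config(config)
  set.seed(seed)
  # ---- inputs ----
  if (is.null(expr)) {
    if (is.null(cfg$counts) || is.null(cfg$conditions))
      stop("missing mandatory input: counts/conditions (or pass 'expr')")
    expr <- read_counts_matrix(cfg$counts, cfg$conditions)
  }
  if (is.null(cn)) {
    if (is.null(cfg$gistic))
      stop("missing mandatory input: gistic (or pass 'cn')")
    cn <- read_gistic_thresholded(cfg$gistic)
  }
  if (is.null(annotation)) {
    if (is.null(cfg$annotation))
      stop("missing mandatory input: annotation (or pass 'annotation')")
    annotation <- read_gene_annotation(cfg$annotation,
                                       dialect = cfg$annotation_dialect %||% "tsv")
  }
  if (is.null(drivers) && !is.null(cfg$drivers))
    drivers <- read_driver_census(cfg$drivers)
  if (is.null(dep) && !is.null(cfg$dep_chronos) && !is.null(cfg$dep_cn_score))
    dep <- read_dependency_input(cfg$dep_chronos, cfg$dep_cn_score)

  notes <- character()
  # ---- preprocessing ----
  raw <- expr
  if (isTRUE(cfg$outlier_removal) && ncol(expr$counts) >= 3) {
    o <- remove_outlier_samples(expr, cor_cut = cfg$cor_cut)
    expr <- o$expr
    if (any(o$report$removed))
      notes <- c(notes, paste0("outliers_removed:",
        paste(o$report$sample_id[o$report$removed], collapse = ",")))
  }
  if (isTRUE(cfg$low_expr_filter) && nrow(expr$counts) >= 4)
    expr <- filter_low_expression(expr, cfg$low_expr_quartile)
  norm <- expr
  if (!identical(cfg$within_lane, "off")) {
    norm <- normalize_within_lane(norm, annotation, covariate = cfg$within_lane,
                                  n_bins = cfg$within_lane_bins)
  } else notes <- c(notes, "within_lane_skipped")
  if (!identical(cfg$between_lane, "off")) {
    norm <- normalize_between_lane(norm, method = cfg$between_lane)
  } else notes <- c(notes, "between_lane_skipped")

  # ---- contrasts ----
  tn <- tumor_normal_contrast(expr, logfc_threshold = cfg$logfc_threshold,
                              fdr_threshold = cfg$fdr_threshold)
  if (is.null(tn)) notes <- c(notes, "tumor_normal_skipped_no_normals")
  scan <- scnv_deg_scan(expr, cn, queried = cfg$queried, mode = cfg$cn_mode,
                        min_altered = cfg$min_altered,
                        logfc_threshold = cfg$logfc_threshold,
                        fdr_threshold = cfg$fdr_threshold,
                        fdr_scope = cfg$fdr_scope, tn = tn)
  records <- scan$records
  if (identical(cfg$tn_policy, "diploid_only") && !is.null(tn) && nrow(records)) {
    # re-run the tumor-vs-normal contrast per record on that gene's diploid
    # tumors only, and relabel the subset accordingly
    for (i in seq_len(nrow(records))) {
      rec <- compute_recurrence(cn, records$gene_id[i], mode = cfg$cn_mode,
                                direction = records$event_type[i])
      dipl <- intersect(rec$diploid_samples, condition_samples(expr, "tumor"))
      tn_i <- tumor_normal_contrast(expr, tumor_samples = dipl,
                                    logfc_threshold = cfg$logfc_threshold,
                                    fdr_threshold = cfg$fdr_threshold)
      if (is.null(tn_i)) next
      row <- tn_i[tn_i$gene_id == records$gene_id[i], ]
      if (nrow(row) == 0) next
      records$log2_fc_tn[i] <- row$log2_fc
      records$fdr_tn[i] <- row$fdr
      sig_sd <- if (records$log2_fc_sd[i] > 0) "up" else "down"
      sig_tn <- if (!row$significant) "none" else if (row$log2_fc > 0) "up" else "down"
      records$subset[i] <- classify_subset(sig_sd, sig_tn)
    }
  }

  # ---- genomic context ----
  tumors <- intersect(condition_samples(expr, "tumor"), colnames(cn$calls))
  cn_tumor <- copy_number_matrix(cn$calls[, tumors, drop = FALSE])
  pairs <- if (!is.null(drivers) && nrow(drivers) > 0) {
    driver_cooccurrence_scan(records, cn_tumor, drivers, mode = cfg$cn_mode,
                             alpha = cfg$cooccur_alpha)
  } else {
    if (nrow(records)) notes <- c(notes, "driver_census_empty")
    empty_pairs()
  }
  windows <- tile_genome(annotation, window_size = cfg$window_size)
  windows <- enriched_windows(windows, records, annotation)
  records <- stratify_and_rank(records, pairs, windows, annotation, drivers)

  # ---- dependency ----
  dep_res <- NULL
  if (!is.null(dep)) {
    dep_res <- dependency_screen(dep,
      genes = intersect(records$gene_id, colnames(dep$chronos)),
      amp_cutoff = cfg$dep_amp_cutoff, dip_low = cfg$dep_dip_low,
      min_group = cfg$dep_min_group, median_diff_cut = cfg$dep_median_diff,
      alpha = cfg$dep_alpha)
  } else notes <- c(notes, "dependency_skipped_no_input")

  # ---- outputs ----
  param_keys <- names(default_config())
  summary <- list(parameters = cfg[setdiff(param_keys, "queried")],
                  queried = if (is.null(cfg$queried)) "all" else cfg$queried,
                  seed = seed,
                  n_samples_raw = ncol(raw$counts),
                  n_samples_used = ncol(expr$counts),
                  n_genes_raw = nrow(raw$counts),
                  n_genes_used = nrow(expr$counts),
                  dispersion_tn = if (!is.null(tn)) attr(tn, "dispersion")$phi else NULL,
                  notes = as.list(notes),
                  skipped_genes = scan$skipped)
  paths <- write_results(records, pairs, windows, dep_res, out_dir,
                         summary = summary)
  skipped_path <- file.path(out_dir, "skipped_genes.tsv")
  write_tsv(scan$skipped, skipped_path)
  paths <- c(paths, skipped = skipped_path)
  invisible(structure(list(records = records, pairs = pairs, windows = windows,
                           dependency = dep_res, skipped = scan$skipped,
                           summary = summary, paths = paths, expr = expr,
                           norm = norm, tn = tn),
                      class = "scnvdeg_run"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scnvdeg_run <- function(x, ...) {
  cat(sprintf("scnvdeg_run: %d SCNV-DEG record(s), %d co-occurrence pair(s), %d enriched window(s)\n",
              nrow(x$records), nrow(x$pairs), sum(x$windows$enriched)))
  if (nrow(x$records)) {
    cat("subset counts:\n")
    print(table(x$records$subset))
    cat("subclass counts:\n")
    print(table(x$records$subclass))
  }
  invisible(x)
}

#' @export
summary.scnvdeg_run <- function(object, ...) {
  print(object)
  if (!is.null(object$dependency) && nrow(object$dependency)) {
    cat(sprintf("dependency screen: %d gene(s), %d significant\n",
                nrow(object$dependency), sum(object$dependency$significant)))
  }
  if (nrow(object$skipped))
    cat(sprintf("%d gene/direction combination(s) skipped\n", nrow(object$skipped)))
  invisible(object)
}

#' Static SCNV-DEG scatter plot
#'
#' Base-graphics rendition of the pipeline's x/y export: x = tumor-versus-
#' normal log2FC, y = SCNV-versus-diploid log2FC, point size scaled by SCNV
#' recurrence, color by event type.
#'
#' @param x An `scnvdeg_run`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.scnvdeg_run <- function(x, ...) {
  r <- x$records
  if (!nrow(r)) {
    graphics::plot.new()
    graphics::title("no SCNV-DEG records")
    return(invisible(x))
  }
  xs <- ifelse(is.na(r$log2_fc_tn), 0, r$log2_fc_tn)
  graphics::plot(xs, r$log2_fc_sd,
                 cex = 0.5 + 3 * r$recurrence,
                 col = ifelse(r$event_type == "amplification", "firebrick", "navy"),
                 pch = 19, xlab = "log2FC tumor vs normal",
                 ylab = "log2FC SCNV vs diploid", ...)
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey60")
  invisible(x)
}
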