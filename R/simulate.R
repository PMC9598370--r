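#' Simulate a paired expression / copy-number tumor cohort with known truth
#'
#' Generates a seeded cohort emulating the statistical structure the pipeline
#' assumes: counts are negative binomial with variance `mu + phi * mu^2`,
#' baseline means are log-normal (`meanlog = log(50)`, `sdlog = 1`) to span
#' realistic count magnitudes, the log2 mean gains the tumor effect in tumor
#' samples and the (signed) dosage effect in copy-number-altered samples, and
#' calls are written as +/-2 for altered tumor samples with optional +/-1
#' call noise that carries no expression effect. Genes are placed uniformly
#' on a toy genome (default 3 chromosomes x 100 Mb, so 10-Mb windows are
#' non-trivial); `cluster_scnv` true SCNV genes can instead be co-located in
#' the first 10 Mb of chromosome 1 to make enriched windows and cis driver
#' linkage constructible. Drivers are labeled half among true SCNV genes and
#' half among null genes.
#'
#' @param n_genes,n_tumor,n_normal Cohort dimensions (defaults 500 / 100 / 8).
#' @param phi Common NB dispersion (default 0.1); 0 gives Poisson counts.
#' @param n_scnv_deg Number of true SCNV-DEGs (default 20).
#' @param dosage_log2fc Absolute log2 expression effect per deep event
#'   (default 2; sign follows the event direction).
#' @param recurrence Fraction of tumor samples altered per true gene
#'   (default 0.3).
#' @param frac_amplified Fraction of true genes that are amplifications, the
#'   rest deletions (default 0.5).
#' @param n_tn_deg,tn_log2fc Number and absolute log2 effect of genes
#'   differentially expressed between tumors and normals independently of
#'   copy number (defaults 0 / 1; signs alternate).
#' @param shallow_noise_rate Per-cell probability of a spurious +/-1 call in
#'   otherwise diploid cells (default 0.02).
#' @param n_drivers Census size (default 10, alternating roles).
#' @param n_chrom,chrom_length Toy genome layout (defaults 3 x 1e8 bp).
#' @param cluster_scnv Number of true SCNV genes forced into the first 10 Mb
#'   of chromosome 1 (default 0).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the arguments.
#' @return List with `expr` ([expression_matrix()]), `cn`
#'   ([copy_number_matrix()]), `annotation` ([gene_annotation()]), `drivers`
#'   (census data frame) and `truth` (per-gene ground-truth data frame with
#'   attributes `phi` and `seed`).
#' @export
simulate_cohort <- function(n_genes = 500, n_tumor = 100, n_normal = 8,
                            phi = 0.1, n_scnv_deg = 20, dosage_log2fc = 2,
                            recurrence = 0.3, frac_amplified = 0.5,
                            n_tn_deg = 0, tn_log2fc = 1,
                            shallow_noise_rate = 0.02, n_drivers = 10,
                            n_chrom = 3, chrom_length = 1e8,
                            cluster_scnv = 0, seed = 1) {
  if (n_scnv_deg > 0 && round(recurrence * n_tumor) < 1)
    stop("inconsistent config: recurrence * n_tumor < 1 for true SCNV genes")
  if (n_scnv_deg > n_genes) stop("n_scnv_deg exceeds n_genes")
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  tumors <- sprintf("T%03d", seq_len(n_tumor))
  normals <- if (n_normal > 0) sprintf("N%03d", seq_len(n_normal)) else character()
  samples <- c(tumors, normals)

  # toy genome placement
  chrom <- paste0("chr", sample.int(n_chrom, n_genes, replace = TRUE))
  width <- round(runif(n_genes, 5e3, 2e5))
  start <- floor(runif(n_genes, 0, chrom_length - width))
  gc <- runif(n_genes, 0.35, 0.65)

  scnv_idx <- seq_len(n_scnv_deg)
  if (cluster_scnv > 0) {
    k <- seq_len(min(cluster_scnv, n_scnv_deg))
    chrom[k] <- "chr1"
    start[k] <- floor(runif(length(k), 0, 1e7 - width[k]))
  }
  direction <- rep("none", n_genes)
  if (n_scnv_deg > 0) {
    n_amp <- round(frac_amplified * n_scnv_deg)
    direction[scnv_idx] <- rep(c("amplification", "deletion"),
                               c(n_amp, n_scnv_deg - n_amp))
  }

  # census: half the drivers among true SCNV genes, half among null genes
  driver_role <- rep("none", n_genes)
  if (n_drivers > 0) {
    n_in <- min(ceiling(n_drivers / 2), n_scnv_deg)
    pool_null <- setdiff(seq_len(n_genes), scnv_idx)
    d_idx <- c(scnv_idx[seq_len(n_in)],
               sample(pool_null, min(n_drivers - n_in, length(pool_null))))
    driver_role[d_idx] <- rep_len(c("oncogene", "tumor_suppressor"), length(d_idx))
  }

  baseline <- rlnorm(n_genes, meanlog = log(50), sdlog = 1)
  # true SCNV-DEGs are expressed genes by definition: a transcript silenced
  # below the low-expression filter cannot display dosage-linked differential
  # expression, so their baselines are drawn from the clearly expressed part
  # of the same log-normal (above its 40th percentile)
  if (n_scnv_deg > 0)
    baseline[scnv_idx] <- stats::qlnorm(runif(n_scnv_deg, 0.4, 1),
                                        meanlog = log(50), sdlog = 1)
  tn_effect <- rep(0, n_genes)
  if (n_tn_deg > 0) {
    tn_idx <- sample.int(n_genes, n_tn_deg)
    tn_effect[tn_idx] <- tn_log2fc * rep_len(c(1, -1), n_tn_deg)
  }

  # copy-number calls
  calls <- matrix(0L, n_genes, n_tumor, dimnames = list(genes, tumors))
  n_alt <- round(recurrence * n_tumor)
  altered_sets <- vector("list", n_genes)
  for (i in scnv_idx) {
    alt <- sample(tumors, n_alt)
    calls[i, alt] <- if (direction[i] == "amplification") 2L else -2L
    altered_sets[[i]] <- alt
  }
  if (shallow_noise_rate > 0) {
    flip <- calls == 0L & matrix(runif(n_genes * n_tumor) < shallow_noise_rate,
                                 n_genes, n_tumor)
    calls[flip] <- sample(c(-1L, 1L), sum(flip), replace = TRUE)
  }

  # expression means and counts
  log2mu <- matrix(log2(baseline), n_genes, length(samples),
                   dimnames = list(genes, samples))
  is_tumor <- samples %in% tumors
  log2mu[, is_tumor] <- log2mu[, is_tumor] + tn_effect
  for (i in scnv_idx) {
    sgn <- if (direction[i] == "amplification") 1 else -1
    log2mu[i, altered_sets[[i]]] <- log2mu[i, altered_sets[[i]]] +
      sgn * dosage_log2fc
  }
  mu <- 2^log2mu
  counts <- if (phi > 0) {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / phi), nrow = n_genes)
  } else {
    matrix(rpois(length(mu), lambda = mu), nrow = n_genes)
  }
  dimnames(counts) <- dimnames(mu)
  storage.mode(counts) <- "integer"
  condition <- setNames(ifelse(is_tumor, "tumor", "normal"), samples)

  annotation <- gene_annotation(data.frame(
    gene_id = genes, chrom = chrom, start = start, end = start + width,
    gc_fraction = gc, driver_role = driver_role, stringsAsFactors = FALSE))
  drivers <- annotation[annotation$driver_role != "none",
                        c("gene_id", "driver_role")]
  rownames(drivers) <- NULL
  truth <- data.frame(
    gene_id = genes, chrom = chrom, start = start, end = start + width,
    baseline_mean = baseline, tumor_log2fc = tn_effect,
    scnv_direction = direction,
    recurrence = ifelse(direction == "none", 0, n_alt / n_tumor),
    dosage_log2fc = ifelse(direction == "none", 0,
                           ifelse(direction == "amplification",
                                  dosage_log2fc, -dosage_log2fc)),
    driver_role = driver_role,
    is_scnv_deg = direction != "none",
    stringsAsFactors = FALSE)
  attr(truth, "phi") <- phi
  attr(truth, "seed") <- seed

  list(expr = expression_matrix(counts, condition, integer_counts = TRUE),
       cn = copy_number_matrix(calls),
       annotation = annotation,
       drivers = drivers,
       truth = truth)
}

#' Simulate DepMap-like dependency tables with known truth
#'
#' For each gene, cell lines are assigned to the amplified or diploid band
#' (copy-number scores drawn uniformly from `[2.5, 4]` and `[1.5, 2.5)`
#' respectively) and Chronos scores are normal with a group-specific mean:
#' diploid lines at `base_mean`, amplified lines at `base_mean - shift` (a
#' positive shift makes amplified lines more dependent).
#'
#' @param shifts Named numeric vector: per-gene median dependency shift.
#' @param n_amplified,n_diploid Lines per band (defaults 20 / 20).
#' @param n_excluded Lines outside both bands, scores in `[0, 1.5)`
#'   (default 0).
#' @param base_mean Diploid Chronos mean (default -0.2).
#' @param sd Chronos standard deviation (default 0.25).
#' @param seed Integer seed.
#' @return List with `dep` (a [dependency_input()]) and `truth` (the shift
#'   vector).
#' @export
simulate_dependency <- function(shifts = c(GENE1 = 0.5), n_amplified = 20,
                                n_diploid = 20, n_excluded = 0,
                                base_mean = -0.2, sd = 0.25, seed = 1) {
  set.seed(seed)
  if (is.null(names(shifts)) || any(!nzchar(names(shifts))))
    stop("'shifts' must be named by gene")
  n_lines <- n_amplified + n_diploid + n_excluded
  lines <- sprintf("CL%03d", seq_len(n_lines))
  genes <- names(shifts)
  chronos <- cn <- matrix(NA_real_, n_lines, length(genes),
                          dimnames = list(lines, genes))
  for (j in seq_along(genes)) {
    grp <- sample(rep(c("amplified", "diploid", "excluded"),
                      c(n_amplified, n_diploid, n_excluded)))
    cn[, j] <- ifelse(grp == "amplified", runif(n_lines, 2.5, 4),
                      ifelse(grp == "diploid", runif(n_lines, 1.5, 2.5 - 1e-9),
                             runif(n_lines, 0, 1.5 - 1e-9)))
    mu <- ifelse(grp == "amplified", base_mean - shifts[j], base_mean)
    chronos[, j] <- rnorm(n_lines, mean = mu, sd = sd)
  }
  list(dep = dependency_input(chronos, cn), truth = shifts)
}

#' Write a simulated cohort as plain-text fixture files
#'
#' Emits the five on-disk formats the readers consume: `counts.tsv`,
#' `conditions.tsv`, `gistic.tsv` (with `Gene Symbol` / `Locus ID` /
#' `Cytoband` metadata columns), `annotation.tsv` (TSV dialect, 1-based
#' inclusive), `drivers.csv`, and `truth.json`.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Target directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
write_cohort_fixtures <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             conditions = file.path(dir, "conditions.tsv"),
             gistic = file.path(dir, "gistic.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             drivers = file.path(dir, "drivers.csv"),
             truth = file.path(dir, "truth.json"))
  cdf <- data.frame(gene_id = rownames(sim$expr$counts), sim$expr$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(cdf, paths["counts"])
  write_tsv(data.frame(sample_id = names(sim$expr$condition),
                       condition = unname(sim$expr$condition),
                       stringsAsFactors = FALSE), paths["conditions"])
  gdf <- data.frame(`Gene Symbol` = rownames(sim$cn$calls),
                    `Locus ID` = seq_len(nrow(sim$cn$calls)),
                    Cytoband = paste0(sim$annotation$chrom[
                      match(rownames(sim$cn$calls), sim$annotation$gene_id)], "p"),
                    sim$cn$calls, check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(gdf, paths["gistic"])
  ann <- as.data.frame(sim$annotation)
  ann$start <- ann$start + 1  # TSV dialect is 1-based inclusive
  write_tsv(ann[, c("gene_id", "chrom", "start", "end", "gc_fraction",
                    "driver_role")], paths["annotation"])
  utils::write.table(sim$drivers, paths["drivers"], sep = ",", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Write simulated dependency tables as CSV fixtures
#'
#' @param dep A [dependency_input()].
#' @param dir Target directory (created if needed).
#' @return Invisibly, the named vector of paths written (`chronos.csv`,
#'   `cn_score.csv`; cell lines in rows, genes in columns).
#' @export
write_dependency_fixtures <- function(dep, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(chronos = file.path(dir, "chronos.csv"),
             cn_score = file.path(dir, "cn_score.csv"))
  for (k in names(paths)) {
    df <- data.frame(cell_line = rownames(dep[[k]]), dep[[k]],
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, paths[k], sep = ",", quote = FALSE,
                       row.names = FALSE, eol = "\n")
  }
  invisible(paths)
}
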