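make_cn <- function(calls) copy_number_matrix(calls)

test_that("binarization encodes altered status for one direction only", {
  calls <- matrix(c(2L, -2L, 0L, 1L), 2, 2,
                  dimnames = list(c("A", "B"), c("T1", "T2")))
  cn <- make_cn(calls)
  bin <- binarize_events(cn, "amplification", "deep")
  expect_equal(unname(bin), matrix(c(1L, 0L, 0L, 0L), 2, 2))
  expect_true(all(binarize_events(make_cn(calls * 0L), "deletion", "deep") == 0L))
})

test_that("the Fisher co-occurrence test matches hypergeometric enumeration", {
  ct <- cooccurrence_test(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(ct$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(ct$relation, "co_occurring")

  ct2 <- cooccurrence_test(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(ct2$p_value, 1)

  ct3 <- cooccurrence_test(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(ct3$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(ct3$relation, "mutually_exclusive")

  set.seed(83)
  for (k in 1:100) {
    n <- sample(4:50, 1)
    a <- rbinom(n, 1, runif(1, 0.1, 0.9))
    b <- rbinom(n, 1, runif(1, 0.1, 0.9))
    ct <- cooccurrence_test(a, b)
    expect_equal(ct$p_value,
                 fisher_oracle(ct$table["both"], ct$table["a_only"],
                               ct$table["b_only"], ct$table["neither"]),
                 tolerance = 1e-10)
  }
})

test_that("driver co-occurrence scan keeps driver-anchored significant pairs only", {
  n <- 100
  samples <- sprintf("T%03d", 1:n)
  calls <- matrix(0L, 4, n, dimnames = list(c("DRV", "G1", "G2", "G3"), samples))
  co <- 1:30
  calls["DRV", co] <- 2L
  calls["G1", co] <- 2L                       # perfectly co-amplified with DRV
  calls["G2", sample(31:100, 20)] <- 2L       # disjoint from DRV
  calls["G3", 1:10] <- 2L
  cn <- make_cn(calls)
  rec <- empty_records()
  for (g in rownames(calls)) {
    rec[nrow(rec) + 1, c("gene_id", "event_type", "recurrence", "fdr_sd")] <-
      list(g, "amplification", 0.2, 1e-4)
  }
  drivers <- data.frame(gene_id = "DRV", driver_role = "oncogene",
                        stringsAsFactors = FALSE)
  set.seed(89)
  pairs <- driver_cooccurrence_scan(rec, cn, drivers, alpha = 0.05)
  expect_true(any(pairs$gene_a == "DRV" & pairs$gene_b == "G1" &
                    pairs$relation == "co_occurring"))
  # pairs of two non-drivers are never tested, whatever their association
  expect_false(any(pairs$gene_a != "DRV" & pairs$gene_b != "DRV"))

  expect_warning(empty <- driver_cooccurrence_scan(rec, cn,
    data.frame(gene_id = character(), driver_role = character())), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("the retention rule controls the false-pair rate under independence", {
  set.seed(97)
  kept <- 0
  for (k in 1:200) {
    a <- rbinom(100, 1, 0.3)
    b <- rbinom(100, 1, 0.3)
    kept <- kept + (cooccurrence_test(a, b)$p_value < 0.05)
  }
  expect_lte(kept / 200, 0.07)  # Fisher is conservative: at most the nominal rate
})

test_that("genome tiling follows the half-open 10-Mb convention", {
  ann <- gene_annotation(data.frame(
    gene_id = c("A", "B"), chrom = "chr1",
    start = c(1e6, 24e6), end = c(1.1e6, 25e6), stringsAsFactors = FALSE))
  w <- tile_genome(ann, 1e7)
  expect_equal(nrow(w), 3)
  expect_equal(w$start, c(0, 1e7, 2e7))
  expect_equal(w$end, c(1e7, 2e7, 25e6))

  # a gene whose midpoint sits exactly at 10 Mb belongs to the second window
  ann2 <- gene_annotation(data.frame(
    gene_id = "M", chrom = "chr1", start = 1e7 - 5e5, end = 1e7 + 5e5,
    stringsAsFactors = FALSE))
  w2 <- tile_genome(ann2, 1e7)
  rec <- empty_records()
  rec[1, c("gene_id", "event_type", "recurrence", "fdr_sd")] <-
    list("M", "amplification", 0.2, 1e-3)
  w2 <- enriched_windows(w2, rec, ann2)
  expect_equal(w2$count, c(0L, 1L))
})

test_that("window enrichment applies the strict greater-than-average rule", {
  fx <- window_fixture(c(5, 3, 3, 1, 0))
  w <- enriched_windows(tile_genome(fx$ann), fx$rec, fx$ann)
  expect_equal(w$count, c(5L, 3L, 3L, 1L, 0L))
  expect_equal(w$candidate, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(w$enriched, c(TRUE, FALSE, FALSE, FALSE, FALSE))

  fx2 <- window_fixture(c(3, 3, 3))
  w2 <- enriched_windows(tile_genome(fx2$ann), fx2$rec, fx2$ann)
  expect_false(any(w2$enriched))

  fx3 <- window_fixture(c(2, 1, 0))
  w3 <- enriched_windows(tile_genome(fx3$ann), fx3$rec, fx3$ann)
  expect_false(any(w3$enriched))
})

test_that("subclass cataloging follows the driver-linkage precedence", {
  ann <- gene_annotation(data.frame(
    gene_id = c("DRV", "TRANS", "CIS", "LONER", "NBR"),
    chrom = c("chr1", "chr2", "chr1", "chr3", "chr1"),
    start = c(1e6, 5e6, 2e6, 9e6, 1.5e6),
    end = c(1.2e6, 5.2e6, 2.2e6, 9.2e6, 1.7e6), stringsAsFactors = FALSE))
  drivers <- data.frame(gene_id = "DRV", driver_role = "oncogene",
                        stringsAsFactors = FALSE)
  rec <- empty_records()
  for (g in ann$gene_id)
    rec[nrow(rec) + 1, c("gene_id", "event_type", "recurrence", "fdr_sd")] <-
      list(g, "amplification", 0.2, 1e-3)
  pairs <- empty_pairs()
  pairs[1, ] <- list("DRV", "TRANS", "amplification", 20L, 2L, 3L, 75L,
                     50, 1e-6, 1e-5, "co_occurring")
  pairs[2, ] <- list("CIS", "DRV", "amplification", 15L, 5L, 5L, 75L,
                     45, 1e-5, 1e-4, "co_occurring")
  windows <- tile_genome(ann)
  windows <- enriched_windows(windows, rec, ann)

  sub <- function(g) catalog_subclass(g, pairs, windows, rec, ann, drivers)
  expect_equal(sub("DRV"), "i")       # census driver
  expect_equal(sub("TRANS"), "ii_b")  # trans-linked to a driver SCNV-DEG
  expect_equal(sub("CIS"), "iii")     # cis co-occurrence with a driver
  expect_equal(sub("LONER"), "ii_a")  # no driver linkage at all

  ranked <- stratify_and_rank(rec, pairs, windows, ann, drivers)
  expect_true(all(ranked$subclass %in% c("i", "ii_a", "ii_b", "iii")))
  expect_setequal(ranked$gene_id, rec$gene_id)
})

test_that("a non-driver sharing an enriched window with a driver is subclass iii", {
  # window 1 holds 4 records incl. a driver; window 2 holds 1; window 3 holds 3
  ann <- gene_annotation(data.frame(
    gene_id = c("DRV", "B1", "B2", "B3", "FAR", "C1", "C2", "C3"),
    chrom = "chr1",
    start = c(1e6, 2e6, 3e6, 4e6, 1.5e7, 2.1e7, 2.2e7, 2.3e7),
    end = c(1e6, 2e6, 3e6, 4e6, 1.5e7, 2.1e7, 2.2e7, 2.3e7) + 1e4,
    stringsAsFactors = FALSE))
  drivers <- data.frame(gene_id = "DRV", driver_role = "oncogene",
                        stringsAsFactors = FALSE)
  rec <- empty_records()
  for (g in ann$gene_id)
    rec[nrow(rec) + 1, c("gene_id", "event_type", "recurrence", "fdr_sd")] <-
      list(g, "amplification", 0.2, 1e-3)
  windows <- enriched_windows(tile_genome(ann), rec, ann)
  expect_equal(windows$enriched, c(TRUE, FALSE, FALSE))
  expect_equal(catalog_subclass("B1", empty_pairs(), windows, rec, ann, drivers),
               "iii")
  # same enriched window but no driver inside -> not iii
  expect_equal(catalog_subclass("C1", empty_pairs(), windows, rec, ann, drivers),
               "ii_a")
})

test_that("stratified ranking orders by recurrence, then FDR, then symbol", {
  ann <- gene_annotation(data.frame(
    gene_id = c("A", "B", "C"), chrom = "chr1",
    start = c(1e6, 2e6, 3e6), end = c(1.1e6, 2.1e6, 3.1e6),
    stringsAsFactors = FALSE))
  rec <- empty_records()
  rec[1, c("gene_id", "event_type", "recurrence", "fdr_sd")] <-
    list("A", "amplification", 0.3, 1e-2)
  rec[2, c("gene_id", "event_type", "recurrence", "fdr_sd")] <-
    list("B", "amplification", 0.3, 1e-4)
  rec[3, c("gene_id", "event_type", "recurrence", "fdr_sd")] <-
    list("C", "amplification", 0.1, 1e-9)
  windows <- enriched_windows(tile_genome(ann), rec, ann)
  ranked <- stratify_and_rank(rec, empty_pairs(), windows, ann, NULL)
  expect_equal(length(unique(ranked$subgroup)), 1)
  expect_equal(ranked$gene_id[order(ranked$rank)], c("B", "A", "C"))

  one <- stratify_and_rank(rec[1, ], empty_pairs(), windows, ann, NULL)
  expect_equal(one$rank, 1L)
})
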