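test_that("copy-number status classification follows mode and direction", {
  expect_equal(classify_cn_status(2L, "deep", "amplification"), "altered")
  expect_equal(classify_cn_status(0L, "deep", "amplification"), "diploid")
  expect_equal(classify_cn_status(0L, "shallow", "deletion"), "diploid")
  expect_equal(classify_cn_status(1L, "deep", "amplification"), "excluded")
  expect_equal(classify_cn_status(1L, "shallow", "amplification"), "altered")
  expect_equal(classify_cn_status(-2L, "deep", "deletion"), "altered")
  expect_equal(classify_cn_status(-2L, "deep", "amplification"), "excluded")
  expect_equal(classify_cn_status(c(1L, 2L), "combined", "amplification"),
               c("altered", "altered"))
  expect_equal(classify_cn_status(-1L, "combined", "deletion"), "altered")
})

test_that("recurrence counts altered samples over all tumor samples", {
  calls <- matrix(0L, 2, 100, dimnames = list(c("A", "B"), sprintf("T%03d", 1:100)))
  calls["A", 1:5] <- 2L
  calls["B", 1:4] <- 1L
  cn <- copy_number_matrix(calls)
  r <- compute_recurrence(cn, "A", "deep", "amplification")
  expect_equal(r$recurrence, 0.05)
  expect_equal(r$altered_samples, sprintf("T%03d", 1:5))

  z <- compute_recurrence(cn, "B", "deep", "amplification")
  expect_equal(z$recurrence, 0)
  expect_equal(length(z$altered_samples), 0)

  deep <- compute_recurrence(cn, "B", "deep", "amplification")$recurrence
  comb <- compute_recurrence(cn, "B", "combined", "amplification")$recurrence
  expect_gte(comb, deep)
  expect_error(compute_recurrence(cn, "Z", "deep", "amplification"), "absent")
})

test_that("the six significance patterns map onto the expression subsets", {
  expect_equal(classify_subset("up", "none"), "a.1")
  expect_equal(classify_subset("down", "none"), "a.2")
  expect_equal(classify_subset("up", "up"), "b.1")
  expect_equal(classify_subset("down", "down"), "b.2")
  expect_equal(classify_subset("up", "down"), "c.1")
  expect_equal(classify_subset("down", "up"), "c.2")
  expect_equal(classify_subset(c("up", "down"), c("none", "up")), c("a.1", "c.2"))
  expect_error(classify_subset("up", "sideways"), "invalid")
})

test_that("the scan recovers a dosage effect and honours the group-size floor", {
  sim <- simulate_cohort(n_genes = 120, n_tumor = 60, n_normal = 6,
                         n_scnv_deg = 4, recurrence = 0.25, n_drivers = 0,
                         shallow_noise_rate = 0, seed = 71)
  tn <- tumor_normal_contrast(sim$expr)
  scan <- scnv_deg_scan(sim$expr, sim$cn, tn = tn)
  truth <- sim$truth[sim$truth$is_scnv_deg, ]
  expect_setequal(scan$records$gene_id, truth$gene_id)
  for (i in seq_len(nrow(scan$records))) {
    tr <- truth[truth$gene_id == scan$records$gene_id[i], ]
    expect_equal(scan$records$event_type[i], tr$scnv_direction)
    expect_lt(abs(abs(scan$records$log2_fc_sd[i]) - 2), 0.5)
    expect_equal(scan$records$recurrence[i], 0.25)
  }
  # every emitted record re-satisfies its thresholds
  expect_true(all(scan$records$fdr_sd < 0.05))
  expect_true(all(abs(scan$records$log2_fc_sd) > 0.58))

  # a gene with too few altered samples is skipped with a logged reason
  calls <- sim$cn$calls
  calls[truth$gene_id[1], ] <- 0L
  alt <- colnames(calls)[1:2]
  calls[truth$gene_id[1], alt] <- 2L
  scan2 <- scnv_deg_scan(sim$expr, copy_number_matrix(calls),
                         queried = truth$gene_id[1], tn = tn)
  expect_equal(nrow(scan2$records), 0)
  expect_match(scan2$skipped$reason[scan2$skipped$direction == "amplification"],
               "group_too_small")
})

test_that("a null copy-number/expression link is rarely reported", {
  emitted <- 0
  for (k in 1:40) {
    set.seed(100 + k)
    mu <- rlnorm(60, log(50), 1)
    counts <- sapply(1:40, function(i) rnbinom(60, mu = mu, size = 10))
    rownames(counts) <- sprintf("g%02d", 1:60)
    colnames(counts) <- sprintf("T%02d", 1:40)
    calls <- matrix(0L, 60, 40, dimnames = dimnames(counts))
    calls[1, sample(40, 12)] <- 2L  # altered group with zero dosage effect
    scan <- scnv_deg_scan(make_expr(counts), copy_number_matrix(calls),
                          queried = "g01")
    emitted <- emitted + nrow(scan$records)
  }
  expect_lte(emitted / 40, 0.1)
})

test_that("absent normals yield no_normal subsets", {
  sim <- simulate_cohort(n_genes = 60, n_tumor = 40, n_normal = 0,
                         n_scnv_deg = 2, n_drivers = 0, seed = 73)
  scan <- scnv_deg_scan(sim$expr, sim$cn, tn = NULL)
  expect_true(nrow(scan$records) > 0)
  expect_true(all(scan$records$subset == "no_normal"))
})

test_that("a cohort with equal tumor and normal baselines lands in subset a", {
  # low recurrence keeps the dosage effect from moving the all-tumors mean
  sim <- simulate_cohort(n_genes = 150, n_tumor = 80, n_normal = 8,
                         n_scnv_deg = 3, recurrence = 0.1, n_drivers = 0,
                         shallow_noise_rate = 0, seed = 79)
  tn <- tumor_normal_contrast(sim$expr)
  scan <- scnv_deg_scan(sim$expr, sim$cn, tn = tn)
  expect_true(nrow(scan$records) > 0)
  expect_true(all(scan$records$subset %in% c("a.1", "a.2")))
})
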