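test_that("library equalization scales to the geometric mean and conserves totals", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), 3,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  eq <- equalize_library_sizes(m)
  expect_equal(eq$counts, m, ignore_attr = TRUE)
  expect_equal(unname(eq$factors), c(1, 1))

  m2 <- cbind(a = c(10, 20, 30), b = 2 * c(10, 20, 30))
  rownames(m2) <- paste0("g", 1:3)
  eq2 <- equalize_library_sizes(m2)
  expect_equal(unname(eq2$factors[2]), sqrt(2) / 2, tolerance = 1e-12)
  for (j in 1:2)
    expect_lte(abs(sum(eq2$counts[, j]) - eq2$target), nrow(m2) / 2)

  expect_error(equalize_library_sizes(cbind(a = c(0, 0), b = c(1, 2))), "zero library")
})

test_that("common dispersion is recovered by conditional maximum likelihood", {
  set.seed(41)
  mu <- rlnorm(600, log(60), 1)
  counts <- sapply(1:20, function(i) rnbinom(600, mu = mu, size = 1 / 0.2))
  rownames(counts) <- paste0("g", 1:600)
  colnames(counts) <- paste0("s", 1:20)
  grp <- rep(c("A", "B"), each = 10)
  est <- estimate_common_dispersion(counts, grp)
  expect_lt(abs(est$phi - 0.2), 0.05)

  pois <- sapply(1:20, function(i) rpois(600, lambda = mu))
  dimnames(pois) <- dimnames(counts)
  est0 <- estimate_common_dispersion(pois, grp)
  expect_lte(est0$phi, 0.01)
  expect_true(est0$at_boundary)
})

test_that("golden-section optimum matches a dense grid search", {
  set.seed(43)
  counts <- sapply(1:10, function(i) rnbinom(60, mu = 40, size = 8))
  rownames(counts) <- paste0("g", 1:60); colnames(counts) <- paste0("s", 1:10)
  grp <- rep(c("A", "B"), each = 5)
  est <- estimate_common_dispersion(counts, grp)
  grid <- seq(-4, 0.6, by = 1e-3)
  ll <- vapply(grid, function(l) cond_loglik_oracle(10^l, counts, grp), numeric(1))
  expect_lt(abs(log10(est$phi) - grid[which.max(ll)]), 2e-3)
})

test_that("the exact test matches enumeration, symmetry and the binomial limit", {
  # spec'd small case: one sample per group, split (8, 2)
  p <- nb_exact_test(8, 2, phi = 0.1)
  expect_equal(p, nb_exact_oracle(8, 2, 0.1), tolerance = 1e-12)

  # symmetry for equal group sizes
  expect_equal(nb_exact_test(c(7, 1), c(2, 0), 0.15),
               nb_exact_test(c(2, 0), c(7, 1), 0.15), tolerance = 1e-14)

  # even total split exactly in half: every outcome is at most as likely
  expect_equal(nb_exact_test(c(3, 2), c(4, 1), 0.2), 1)

  # T = 0 convention
  expect_equal(nb_exact_test(c(0, 0), c(0, 0), 0.1), 1)

  # phi -> 0 converges to the two-sided binomial test
  set.seed(47)
  for (k in 1:20) {
    n_a <- sample(2:6, 1); n_b <- sample(2:6, 1)
    ca <- rpois(n_a, 8); cb <- rpois(n_b, 8)
    p_nb <- nb_exact_test(ca, cb, 1e-8)
    p_bin <- nb_exact_oracle(ca, cb, 0)
    expect_lt(abs(p_nb - p_bin), 1e-6)
  }
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(53)
  for (k in 1:20) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone along sorted p
  }
})

test_that("differential expression detects truth, is antisymmetric, and is null-safe", {
  set.seed(59)
  mu <- rlnorm(200, log(50), 1)
  fc <- rep(1, 200); fc[1:10] <- 4
  counts_a <- sapply(1:6, function(i) rnbinom(200, mu = mu, size = 10))
  counts_b <- sapply(1:6, function(i) rnbinom(200, mu = mu * fc, size = 10))
  expr <- make_expr(cbind(counts_a, counts_b))
  a_ids <- colnames(expr$counts)[1:6]; b_ids <- colnames(expr$counts)[7:12]
  de <- differential_expression(expr, a_ids, b_ids)
  expect_gte(mean(de$significant[1:10]), 0.9)
  expect_lte(sum(de$significant[-(1:10)]), 4)

  swapped <- differential_expression(expr, b_ids, a_ids)
  expect_equal(swapped$log2_fc, -de$log2_fc, tolerance = 1e-12)
  expect_equal(swapped$p_value, de$p_value, tolerance = 1e-12)

  # two identical groups: a null contrast yields no significant gene
  dup <- make_expr(cbind(counts_a, counts_a))
  null_de <- differential_expression(dup, colnames(dup$counts)[1:6],
                                     colnames(dup$counts)[7:12])
  expect_false(any(null_de$significant))
  expect_true(all(abs(null_de$log2_fc) < 1e-12))

  expect_error(differential_expression(expr, a_ids, a_ids), "overlap")
})

test_that("dispersion and p-values agree with the edgeR exact-test route", {
  set.seed(61)
  v <- rnbinom(200, mu = 50, size = 5)
  counts <- sapply(1:10, function(i) sample(v))  # equal library sizes by design
  rownames(counts) <- sprintf("g%03d", 1:200)
  colnames(counts) <- sprintf("s%02d", 1:10)
  grp <- rep(c("A", "B"), each = 5)
  est <- estimate_common_dispersion(counts, grp)

  d <- edgeR::DGEList(counts = counts, group = grp)
  d <- edgeR::estimateCommonDisp(d)
  expect_equal(est$phi, d$common.dispersion, tolerance = 0.02)

  d$common.dispersion <- est$phi
  et <- edgeR::exactTest(d, rejection.region = "smallp")
  p_ours <- vapply(seq_len(nrow(counts)), function(i)
    nb_exact_test(counts[i, 1:5], counts[i, 6:10], est$phi), numeric(1))
  expect_equal(p_ours, et$table$PValue, tolerance = 1e-8, ignore_attr = TRUE)
})
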