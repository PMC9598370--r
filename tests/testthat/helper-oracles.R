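# Independent oracles used across test files. Each recomputes the target
# quantity by a different route than the package implementation.

# conditional NB split test by direct enumeration of normalized dnbinom
# products (binomial at phi = 0); mu is arbitrary by conditioning
nb_exact_oracle <- function(counts_a, counts_b, phi, mu = 7.3) {
  n_a <- length(counts_a); n_b <- length(counts_b)
  s_obs <- sum(counts_a); t_tot <- s_obs + sum(counts_b)
  if (t_tot == 0) return(1)
  s <- 0:t_tot
  if (phi == 0) {
    pr <- dbinom(s, t_tot, n_a / (n_a + n_b))
  } else {
    pr <- dnbinom(s, size = n_a / phi, mu = n_a * mu) *
      dnbinom(t_tot - s, size = n_b / phi, mu = n_b * mu)
  }
  pr <- pr / sum(pr)
  sum(pr[pr <= pr[s_obs + 1] * (1 + 1e-8)])
}

# two-sided Fisher p for a 2x2 table by hypergeometric enumeration
fisher_oracle <- function(n_both, n_a_only, n_b_only, n_neither) {
  ka <- n_both + n_a_only              # altered-in-A margin
  kb <- n_both + n_b_only              # altered-in-B margin
  n <- n_both + n_a_only + n_b_only + n_neither
  x <- max(0, ka + kb - n):min(ka, kb) # support of the 'both' cell
  pr <- dhyper(x, kb, n - kb, ka)
  sum(pr[pr <= dhyper(n_both, kb, n - kb, ka) * (1 + 1e-7)])
}

# BH step-up by the literal definition: q_i = min_{j >= i} p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(1, q)[order(o)]
}

# conditional NB log-likelihood via dnbinom ratios (mean cancels under equal
# library sizes); used as the grid-search oracle for dispersion estimation
cond_loglik_oracle <- function(phi, counts, groups, mu = 10) {
  r <- 1 / phi
  ll <- 0
  for (g in unique(groups)) {
    y <- counts[, groups == g, drop = FALSE]
    n <- ncol(y)
    z <- rowSums(y)
    ll <- ll + sum(dnbinom(y, size = r, mu = mu, log = TRUE)) -
      sum(dnbinom(z, size = n * r, mu = n * mu, log = TRUE))
  }
  ll
}

# small deterministic expression matrix builder
make_expr <- function(counts, condition = NULL) {
  if (is.null(rownames(counts)) || any(!nzchar(rownames(counts))))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)) || any(!nzchar(colnames(counts))))
    colnames(counts) <- sprintf("s%03d", seq_len(ncol(counts)))
  if (is.null(condition)) condition <- rep("tumor", ncol(counts))
  expression_matrix(counts, condition)
}
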