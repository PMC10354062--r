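# Independent brute-force oracles. These deliberately avoid the code paths
# (and distribution functions) used by the implementation: tail sums are
# built from exact binomial coefficients via choose(), enumeration is over
# whole outcome tables.

# Upper-tail hypergeometric P(X >= k) by direct summation of
# choose(M,i)*choose(N-M,n-i)/choose(N,n).
oracle_hyper_tail <- function(N, M, n, k) {
  if (k == 0) return(1)
  i <- k:min(n, M)
  sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}

# Exact HWE test by enumeration of every genotype configuration compatible
# with the observed allele counts; probability of a configuration
# (nAA, nAa, naa) conditional on allele counts is proportional to
# n! * 2^het / (nAA! nAa! naa!).
oracle_hwe <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_alt <- 2 * n_hom_alt + n_het
  hets <- 0:min(n_alt, 2 * n - n_alt)
  hets <- hets[(n_alt - hets) %% 2 == 0]
  weight <- function(h) {
    aa <- (n_alt - h) / 2
    AA <- n - aa - h
    if (AA < 0) return(0)
    exp(lfactorial(n) - lfactorial(AA) - lfactorial(h) - lfactorial(aa) +
          h * log(2))
  }
  w <- vapply(hets, weight, numeric(1))
  p <- w / sum(w)
  obs <- p[hets == n_het]
  sum(p[p <= obs * (1 + 1e-9)])
}

# Two-sided Fisher exact p by enumeration of all 2x2 tables with the
# observed margins; point probabilities from choose() products.
oracle_fet2 <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; m <- a + c
  xs <- max(0, m - n2):min(m, n1)
  pr <- choose(n1, xs) * choose(n2, m - xs) / choose(n1 + n2, m)
  obs <- pr[xs == a]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# BH step-up by hand: q_(i) = min_{j >= i} p_(j) * m / j, mapped back to
# input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Welch unequal-variance t-test from the closed form.
oracle_welch <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(statistic = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
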