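# Brute-force two-sided Fisher oracle: enumerate every table sharing the
# margins, point probabilities from log-binomial coefficients (independent
# of the package's dhyper-based implementation), sum those not exceeding
# the observed probability (relative tie tolerance as in the implementation).
oracle_fisher <- function(a, b, c, d, rel_tol = 1e-7) {
  m <- a + c; n <- b + d; k <- a + b
  x <- max(0, k - n):min(k, m)
  logp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  p_obs <- logp[x == a]
  min(1, sum(exp(logp[logp <= p_obs + log1p(rel_tol)])))
}

# Two-sided p for every feasible value of cell `a` under margins
# (carriers m, non-carriers n, cases k); vectorized via sorted cumsum.
oracle_fisher_all <- function(m, n, k, rel_tol = 1e-7) {
  x <- max(0, k - n):min(k, m)
  logp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  ord <- order(logp)
  cs <- cumsum(exp(logp[ord]))
  sorted_logp <- logp[ord]
  p <- vapply(logp, function(lp) {
    cs[findInterval(lp + log1p(rel_tol), sorted_logp)]
  }, numeric(1))
  list(a = x, p = pmin(1, p))
}
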