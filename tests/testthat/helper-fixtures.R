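# shared fixtures and independent oracles

random_expr <- function(ngenes = 20, nsamples = 5, seed = 1, unit = "counts") {
  set.seed(seed)
  v <- matrix(rpois(ngenes * nsamples, 50) + 1, ngenes, nsamples,
              dimnames = list(sprintf("G%03d", seq_len(ngenes)),
                              sprintf("s%02d", seq_len(nsamples))))
  expression_matrix(v * 1.0, unit)
}

# five-profile fixture: one profile per priority pattern plus a mixed one.
# With all five ANOVA-defined, the Bonferroni family size is 5:
#   A raw p ~ 3e-7  -> adj ~ 1.6e-6  -> priority 1
#   B raw p = 0.0141 -> adj = 0.0705 -> priority 2
#   C F = 0, p = 1, all ranks >= 85  -> priority 4
#   D F = 0, p = 1, all ranks <= 15  -> priority 5
#   E mixed mid ranks, p large       -> priority 3
priority_fixture <- function() {
  list(
    A = profile_record("A", c(1, 2, 3, 97, 98, 99), rep(c("g1", "g2"), each = 3)),
    B = profile_record("B", c(10, 20, 30, 44, 54, 64), rep(c("g1", "g2"), each = 3)),
    C = profile_record("C", rep(c(85, 90, 95, 88, 92), 2), rep(c("g1", "g2"), each = 5)),
    D = profile_record("D", rep(c(5, 10, 15, 8, 12), 2), rep(c("g1", "g2"), each = 5)),
    E = profile_record("E", c(30, 55, 70, 40, 60, 35, 65, 45, 50, 58),
                       rep(c("g1", "g2"), each = 5))
  )
}

# brute-force doubly-trimmed weighted mean of M-values against a reference,
# written with explicit sorting/selection (independent of the package's
# rank-based route)
oracle_tmm_factor <- function(obs, ref, logratio_trim = 0.3, sum_trim = 0.05) {
  n_obs <- sum(obs); n_ref <- sum(ref)
  pos <- obs > 0 & ref > 0
  o <- obs[pos]; r <- ref[pos]
  m <- log2((o / n_obs) / (r / n_ref))
  a <- 0.5 * log2((o / n_obs) * (r / n_ref))
  if (max(abs(m)) < 1e-6) return(1)
  w <- (n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r)
  n <- length(m)
  keep_m <- seq_len(n) %in% order(m)[(floor(n * logratio_trim) + 1):(n - floor(n * logratio_trim))]
  keep_a <- seq_len(n) %in% order(a)[(floor(n * sum_trim) + 1):(n - floor(n * sum_trim))]
  keep <- keep_m & keep_a
  2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
}

# weighted least squares by explicit normal equations
oracle_wls <- function(y, X, w) {
  XtWX <- t(X) %*% (X * w)
  solve(XtWX, t(X) %*% (w * y))[, 1]
}

# upper-tail F p-value via the beta-distribution route
oracle_pf_upper <- function(f, d1, d2) pbeta(d2 / (d2 + d1 * f), d2 / 2, d1 / 2)

# upper-tail chi-square p-value via the gamma-distribution route
oracle_pchisq_upper <- function(x, df) pgamma(x, shape = df / 2, scale = 2,
                                              lower.tail = FALSE)

# exact hypergeometric upper tail by enumeration of overlap counts
oracle_hyper_upper <- function(overlap, set_size, universe, list_size) {
  ks <- overlap:min(set_size, list_size)
  sum(choose(set_size, ks) * choose(universe - set_size, list_size - ks)) /
    choose(universe, list_size)
}

sim_labels <- function(ds, thr = contamination_thresholds()) {
  assign_groups(log2_expression(cpm(ds$counts), thr$marker), thr)
}
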