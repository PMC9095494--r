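test_that("one-way ANOVA matches hand computation and base R on the toy groups", {
  res <- one_way_anova(c(10, 20, 30, 70, 80, 90), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 54)          # SSB = 5400, SSW = 400, df (1, 4)
  expect_equal(res$df, c(1, 4))
  expect_equal(res$p_value, 0.00182626066826, tolerance = 1e-9)
  base_fit <- anova(lm(y ~ g, data.frame(y = c(10, 20, 30, 70, 80, 90),
                                         g = rep(c("a", "b"), each = 3))))
  expect_equal(res$statistic, base_fit$`F value`[1])
  expect_equal(res$p_value, base_fit$`Pr(>F)`[1])
})

test_that("ANOVA flags degenerate inputs as NA instead of erroring", {
  expect_true(is.na(one_way_anova(1:5, rep("only", 5))$p_value))
  expect_true(is.na(one_way_anova(rep(3, 6), rep(c("a", "b"), 3))$p_value))
  # one observation per group leaves no residual df
  expect_true(is.na(one_way_anova(c(1, 2, 3), c("a", "b", "c"))$p_value))
  # zero within-group variance but real separation: p -> 0
  sep <- one_way_anova(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_equal(sep$p_value, 0)
})

test_that("ANOVA F equals squared pooled t and is permutation invariant", {
  for (seed in 1:20) {
    set.seed(seed)
    y <- rnorm(12); g <- rep(c("a", "b"), each = 6)
    res <- one_way_anova(y, g)
    tt <- t.test(y ~ g, var.equal = TRUE)
    expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
    perm <- sample(12)
    expect_equal(one_way_anova(y[perm], g[perm])$statistic, res$statistic,
                 tolerance = 1e-12)
  }
})

test_that("Bonferroni uses the non-missing family size and caps at 1", {
  expect_equal(bonferroni(rep(0.0001, 143))[1], 0.0143)
  expect_equal(bonferroni(rep(0.01, 143))[1], 1)
  p <- c(0.0001, NA, 0.002)
  adj <- bonferroni(p)
  expect_equal(adj, c(0.0002, NA, 0.004))   # m = 2 non-NA tests
  expect_true(all(is.na(bonferroni(c(NA_real_, NA_real_)))))
  expect_error(bonferroni(c(0.5, 1.5)), "\\[0, 1\\]")
})

test_that("BH adjustment matches the step-up definition and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  for (seed in 1:100) {
    set.seed(seed)
    p <- runif(sample(2:40, 1))^2
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))
    expect_equal(adj, p.adjust(p, "BH"), tolerance = 1e-12)
  }
  # NA propagation with reduced family
  withNA <- bh_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(withNA[2]))
  expect_equal(withNA[c(1, 3)], p.adjust(c(0.01, 0.04), "BH"))
})

test_that("Kruskal-Wallis reproduces the rank-sum toy and kruskal.test", {
  res <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 27 / 7, tolerance = 1e-12)   # H = 3.857...
  expect_equal(res$df, 1)
  expect_equal(res$p_value, 0.0495346134356, tolerance = 1e-9)
  for (seed in 1:50) {
    set.seed(seed)
    y <- sample(1:6, 15, replace = TRUE)    # heavy ties
    g <- sample(c("a", "b", "c"), 15, replace = TRUE)
    if (length(unique(g)) < 2 || length(unique(y)) < 2) next
    mine <- kruskal_wallis(y, g)
    ref <- kruskal.test(y, factor(g))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_true(is.na(kruskal_wallis(rep(2, 4), c("a", "a", "b", "b"))$p_value))
})

test_that("Kruskal-Wallis type-I error is near nominal under the null", {
  set.seed(123)
  rejections <- 0L
  nsim <- 2000
  for (i in seq_len(nsim)) {
    y <- rnorm(24)
    g <- rep(c("a", "b", "c"), each = 8)
    if (kruskal_wallis(y, g)$p_value < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / nsim
  # binomial 3-sigma band around 0.05
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / nsim))
})

test_that("p-values agree with independent distribution routes to 1e-10", {
  for (seed in 1:100) {
    set.seed(seed)
    y <- rnorm(15, sd = runif(1, 0.5, 2))
    g <- sample(c("a", "b", "c"), 15, replace = TRUE)
    if (min(table(g)) < 2) next
    a <- one_way_anova(y, g)
    expect_equal(a$p_value, oracle_pf_upper(a$statistic, a$df[1], a$df[2]),
                 tolerance = 1e-10)
    k <- kruskal_wallis(round(y, 1), g)
    expect_equal(k$p_value, oracle_pchisq_upper(k$statistic, k$df),
                 tolerance = 1e-10)
  }
})

test_that("hypergeometric enrichment matches exact enumeration", {
  sets <- gene_sets(list(S = sprintf("g%02d", 1:5)))
  universe <- sprintf("g%02d", 1:20)
  de <- sprintf("g%02d", c(1:4, 20))     # overlap 4 of list 5
  res <- hypergeometric_enrichment(de, sets, universe)
  expect_equal(res$overlap, 4L)
  expect_equal(res$p_value, 76 / 15504, tolerance = 1e-12)

  # brute-force enumeration oracle on random small instances
  for (seed in 1:30) {
    set.seed(seed)
    u <- sprintf("u%02d", 1:sample(8:15, 1))
    s <- sample(u, sample(2:5, 1))
    l <- sample(u, sample(2:6, 1))
    got <- hypergeometric_enrichment(l, gene_sets(list(S = s)), u)
    ov <- length(intersect(s, l))
    want <- if (ov == 0) 1 else oracle_hyper_upper(ov, length(s), length(u), length(l))
    expect_equal(got$p_value, want, tolerance = 1e-12)
  }
})

test_that("enrichment degenerate cases: empty list and saturated set", {
  u <- sprintf("g%d", 1:10)
  sets <- gene_sets(list(all = u, half = u[1:5]))
  none <- hypergeometric_enrichment(character(), sets, u)
  expect_true(all(none$p_value == 1))
  sat <- hypergeometric_enrichment(u, gene_sets(list(all = u)), u)
  expect_equal(sat$p_value, 1)
  expect_error(hypergeometric_enrichment(u, sets, character()), "universe")
  expect_error(hypergeometric_enrichment(c(u, "stray"), sets, u), "stray")
})
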