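test_that("cpm scales columns to one million and guards units", {
  v <- matrix(c(1, 3), 2, 1, dimnames = list(c("A", "B"), "s1"))
  m <- cpm(expression_matrix(v, "counts"))
  expect_equal(unclass(m)[, 1], c(A = 250000, B = 750000))
  expect_equal(expr_unit(m), "CPM")
  expect_error(cpm(m), "CPM")
  big <- random_expr(40, 6, seed = 4)
  expect_equal(unname(colSums(cpm(big))), rep(1e6, 6))
  zero <- expression_matrix(matrix(c(0, 0, 1, 2), 2, 2,
                                   dimnames = list(c("A", "B"), c("bad", "ok"))),
                            "counts")
  expect_error(cpm(zero), "bad")
})

test_that("expression filter applies strict CPM > cutoff in enough samples", {
  v <- matrix(c(3, 3, 3, 0,
                3, 3, 0, 0,
                2, 2, 2, 2), 3, 4, byrow = TRUE,
              dimnames = list(c("kept", "dropped", "boundary"), paste0("s", 1:4)))
  m <- structure(v, unit = "CPM", class = c("cp_expr", "matrix", "array"))
  mask <- filter_by_cpm(m, min_cpm = 2, min_samples = 3)
  expect_identical(unname(mask), c(TRUE, FALSE, FALSE))
  expect_error(filter_by_cpm(m[, 1:2], min_samples = 3), "fewer samples")
})

test_that("TMM factors: symmetry, depth-only differences, geometric mean 1", {
  v <- matrix(rpois(40, 100) + 1, 20, 2,
              dimnames = list(sprintf("g%d", 1:20), c("s1", "s2")))
  v[, 2] <- v[, 1]
  same <- tmm_factors(expression_matrix(v * 1.0, "counts"))
  expect_equal(same$tmm_factor, c(1, 1))

  v[, 2] <- 2 * v[, 1]      # pure depth difference: M identically zero
  depth <- tmm_factors(expression_matrix(v * 1.0, "counts"))
  expect_equal(depth$tmm_factor, c(1, 1))

  for (seed in 1:10) {
    m <- random_expr(60, 5, seed = seed)
    f <- tmm_factors(m)$tmm_factor
    expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
    expect_true(all(f > 0))
  }
})

test_that("TMM factor equals the brute-force trimmed weighted mean", {
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    v <- matrix(rpois(2 * n, 80) + 1, n, 2,
                dimnames = list(sprintf("g%d", 1:n), c("ref", "obs")))
    v[sample(n, 3), 2] <- v[sample(n, 3), 2] * 20   # composition outliers
    m <- expression_matrix(v * 1.0, "counts")
    fac <- tmm_factors(m)
    uq <- apply(sweep(v, 2, colSums(v), "/"), 2, quantile, probs = 0.75)
    ref <- which.min(abs(uq - mean(uq)))
    obs <- setdiff(1:2, ref)
    raw <- oracle_tmm_factor(v[, obs], v[, ref])
    want <- c(1, raw) / exp(mean(log(c(1, raw))))   # geometric-mean rescale
    expect_equal(fac$tmm_factor[c(ref, obs)], want, tolerance = 1e-10)
  }
})

test_that("TMM factors agree with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  for (seed in 1:8) {
    set.seed(seed)
    n <- 200
    v <- matrix(rnbinom(n * 4, mu = exp(runif(n * 4, 1, 6)), size = 5), n, 4,
                dimnames = list(sprintf("g%d", 1:n), paste0("s", 1:4)))
    v <- v[rowSums(v > 0) == 4, , drop = FALSE]
    mine <- tmm_factors(expression_matrix(v * 1.0, "counts"))
    ref <- edgeR::calcNormFactors(v, method = "TMM")
    expect_equal(mine$tmm_factor, unname(ref), tolerance = 1e-8)
  }
})

test_that("voom log-cpm offset formula and weight positivity", {
  set.seed(10)
  n <- 200
  v <- matrix(rnbinom(n * 6, mu = 50, size = 10), n, 6,
              dimnames = list(sprintf("g%d", 1:n), paste0("s", 1:6)))
  v[1, 1] <- 0
  m <- expression_matrix(v * 1.0, "counts")
  design <- cbind(intercept = 1, grp = rep(0:1, each = 3))
  out <- voom_transform(m, NULL, design)
  lib <- colSums(v)
  expect_equal(out$log_cpm[1, 1], log2(0.5 / (unname(lib[1]) + 1) * 1e6))
  expect_true(all(is.finite(out$weights) & out$weights > 0))
  expect_error(voom_transform(m[, c(1, 4)], NULL, design[c(1, 4), ]),
               "residual")
})

test_that("voom matches the limma reference implementation", {
  skip_if_not_installed("limma")
  set.seed(11)
  n <- 300
  v <- matrix(rnbinom(n * 8, mu = exp(runif(n * 8, 2, 7)), size = 8), n, 8,
              dimnames = list(sprintf("g%d", 1:n), paste0("s", 1:8)))
  v <- v[rowSums(v) > 0, ]
  m <- expression_matrix(v * 1.0, "counts")
  design <- cbind(intercept = 1, grp = rep(0:1, each = 4))
  fac <- tmm_factors(m)
  mine <- voom_transform(m, fac, design, span = 0.5)
  ref <- limma::voom(v, design, lib.size = colSums(v) * fac$tmm_factor,
                     span = 0.5)
  expect_equal(mine$log_cpm, ref$E, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(mine$weights, ref$weights, ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("voom weights are near-constant for homoskedastic Poisson counts", {
  set.seed(12)
  n <- 2000
  v <- matrix(rpois(n * 6, lambda = 60), n, 6,
              dimnames = list(sprintf("g%d", 1:n), paste0("s", 1:6)))
  m <- expression_matrix(v * 1.0, "counts")
  design <- cbind(intercept = 1, grp = rep(0:1, each = 3))
  out <- voom_transform(m, NULL, design)
  cv <- sd(out$weights) / mean(out$weights)
  expect_lt(cv, 0.2)
})

test_that("gene-wise weighted LS matches the normal-equations oracle", {
  set.seed(13)
  n_s <- 8
  design <- cbind(intercept = 1, grp = rep(0:1, each = 4), cov = rnorm(n_s))
  y <- matrix(rnorm(20 * n_s), 20, n_s,
              dimnames = list(sprintf("g%d", 1:20), paste0("s", 1:n_s)))
  w <- matrix(runif(20 * n_s, 0.2, 5), 20, n_s, dimnames = dimnames(y))
  fit <- fit_weighted_lm(y, w, design)
  for (g in 1:20) {
    expect_equal(unname(fit$coefficients[g, ]),
                 unname(oracle_wls(y[g, ], design, w[g, ])), tolerance = 1e-8)
  }
  # unit weights, two groups, no covariates: coefficient is the mean difference
  d2 <- cbind(intercept = 1, grp = rep(0:1, each = 4))
  f2 <- fit_weighted_lm(y, NULL, d2)
  expect_equal(unname(f2$coefficients[, "grp"]),
               unname(rowMeans(y[, 5:8]) - rowMeans(y[, 1:4])), tolerance = 1e-12)
  # doubling the weights changes nothing about the coefficients
  f3 <- fit_weighted_lm(y, 2 * w, design)
  expect_equal(f3$coefficients, fit$coefficients, tolerance = 1e-12)

  bad <- cbind(intercept = 1, grp = rep(0:1, each = 4),
               grp2 = rep(0:1, each = 4))
  expect_error(fit_weighted_lm(y, NULL, bad), "grp2")
})

test_that("variance moderation matches limma's squeezeVar and its limits", {
  skip_if_not_installed("limma")
  set.seed(14)
  df <- 6
  s2 <- 2 * df / rchisq(300, df) * rchisq(300, df) / df   # heterogeneous
  mine <- moderate_variances(s2, df)
  ref <- limma::squeezeVar(s2, df)
  expect_equal(mine$df_prior, ref$df.prior, tolerance = 1e-6)
  expect_equal(mine$s2_prior, ref$var.prior, tolerance = 1e-6)
  expect_equal(mine$s2_post, ref$var.post, tolerance = 1e-6)

  same <- moderate_variances(rep(1.7, 50), df)
  expect_true(is.infinite(same$df_prior))
  expect_equal(same$s2_post, rep(1.7, 50))
})

test_that("moment estimator recovers the variance prior", {
  # variances generated from a scaled inverse-chi-square prior (d0 = 4,
  # s0^2 = 2) observed through chi-square(df) sampling noise
  set.seed(15)
  d0 <- 4; s02 <- 2; df <- 10
  d0_hat <- s02_hat <- numeric(100)
  for (i in 1:100) {
    sigma2 <- d0 * s02 / rchisq(200, d0)
    s2 <- sigma2 * rchisq(200, df) / df
    est <- moderate_variances(s2, df)
    d0_hat[i] <- est$df_prior
    s02_hat[i] <- est$s2_prior
  }
  expect_lt(abs(mean(d0_hat) - d0), 1)
  expect_lt(abs(mean(s02_hat) - s02) / s02, 0.2)
})
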