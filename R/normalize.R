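#' Counts per million
#'
#' Per sample, `value * 1e6 / column_sum`. Accepts raw counts or TPM (the
#' survey pipeline deliberately feeds TPM through the counts machinery, as the
#' depth information in TPM columns is already removed but the downstream
#' filters and normalization expect the CPM scale). Refuses input already in
#' CPM or log2 units.
#'
#' @param m `cp_expr` with unit counts or TPM.
#' @return `cp_expr` with unit CPM; columns sum to 1e6.
#' @export
cpm <- function(m) {
  if (!expr_unit(m) %in% c("counts", "TPM"))
    stop("cpm expects counts or TPM input, got '", expr_unit(m), "'", call. = FALSE)
  cs <- colSums(m)
  if (any(cs == 0))
    stop("zero column sum for sample(s): ",
         paste(colnames(m)[cs == 0], collapse = ", "), call. = FALSE)
  expression_matrix(sweep(unclass(m), 2, cs, "/") * 1e6, "CPM")
}

#' Expression filter: minimum CPM in a minimum number of samples
#'
#' Keeps a gene iff its CPM exceeds `min_cpm` (strictly) in at least
#' `min_samples` samples — the usual low-expression filter before
#' normalization and linear modeling.
#'
#' @param m `cp_expr` with unit CPM.
#' @param min_cpm CPM threshold (strict ">").
#' @param min_samples minimum number of samples above threshold.
#' @return logical gene mask, named by gene id.
#' @export
filter_by_cpm <- function(m, min_cpm = 2, min_samples = 3) {
  if (expr_unit(m) != "CPM") stop("filter_by_cpm expects CPM input", call. = FALSE)
  if (ncol(m) < min_samples)
    stop("fewer samples (", ncol(m), ") than min_samples (", min_samples, ")",
         call. = FALSE)
  mask <- rowSums(unclass(m) > min_cpm) >= min_samples
  stats::setNames(mask, rownames(m))
}

# M/A/weight triple of sample `obs` against `ref` over genes positive in both;
# weights are the inverse binomial asymptotic variances of M (delta method)
.tmm_ma <- function(obs, ref, n_obs, n_ref) {
  pos <- obs > 0 & ref > 0
  if (!any(pos)) return(NULL)
  o <- obs[pos]; r <- ref[pos]
  m <- log2((o / n_obs) / (r / n_ref))
  a <- 0.5 * log2((o / n_obs) * (r / n_ref))
  v <- (n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r)
  list(m = m, a = a, v = v)
}

# doubly trimmed weighted mean of M: drop logratio_trim of each M tail and
# sum_trim of each A tail (rank-based, as in the canonical TMM definition)
.tmm_one <- function(obs, ref, n_obs, n_ref, logratio_trim = 0.3, sum_trim = 0.05) {
  ma <- .tmm_ma(obs, ref, n_obs, n_ref)
  if (is.null(ma))
    stop("sample shares no positive genes with the reference", call. = FALSE)
  if (max(abs(ma$m)) < 1e-6) return(1)           # columns proportional
  n <- length(ma$m)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1;      hi_a <- n + 1 - lo_a
  rm_ <- rank(ma$m); ra <- rank(ma$a)
  keep <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  f <- sum(ma$m[keep] / ma$v[keep]) / sum(1 / ma$v[keep])
  if (!is.finite(f)) f <- 0
  2^f
}

#' Trimmed mean of M-values normalization factors
#'
#' Between-sample scaling factors robust to composition bias. The reference is
#' the sample whose upper-quartile CPM is closest to the mean upper quartile.
#' For every sample, gene-wise log ratios M and average abundances A are
#' computed against the reference over genes positive in both; the most
#' extreme 30% of M (each tail) and 5% of A (each tail) are trimmed and the
#' factor is `2^` the precision-weighted mean of the remaining M (inverse
#' asymptotic-variance weights). Factors are rescaled so their geometric mean
#' is exactly 1.
#'
#' @param counts `cp_expr` (counts, or TPM run through the counts path).
#' @param logratio_trim,sum_trim tail-trim fractions for M and A.
#' @return data.frame: sample_id, library_size, tmm_factor.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  if (ncol(counts) < 2) stop("TMM needs >=2 samples", call. = FALSE)
  x <- unclass(counts)
  lib <- colSums(x)
  if (any(lib <= 0)) stop("non-positive library size", call. = FALSE)
  uq <- apply(sweep(x, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(x)), function(j) {
    if (j == ref) 1
    else .tmm_one(x[, j], x[, ref], lib[j], lib[ref], logratio_trim, sum_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  data.frame(sample_id = colnames(x), library_size = lib, tmm_factor = f,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Log-CPM with mean-variance precision weights
#'
#' The counts are transformed to `log2((count + 0.5) / (lib * factor + 1) *
#' 1e6)`; a gene-wise linear model under `design` yields residual standard
#' deviations whose square roots are smoothed against average log2 count size
#' with lowess (span `span`). Each observation's weight is the inverse fourth
#' power of the trend value at its fitted log2 count — observations on the
#' noisy low-count shoulder of the trend are down-weighted in the subsequent
#' weighted regression.
#'
#' @param counts post-filter `cp_expr`.
#' @param factors data.frame from [tmm_factors()] (or NULL for unit factors).
#' @param design numeric design matrix, rows = samples.
#' @param span lowess span for the mean-variance trend.
#' @return list: `log_cpm` (genes x samples), `weights` (same shape, positive),
#'   `trend` (the lowess curve: x = average log2 count, y = sqrt(sd)).
#' @export
voom_transform <- function(counts, factors = NULL, design, span = 0.5) {
  x <- unclass(counts)
  lib <- colSums(x)
  fac <- if (is.null(factors)) rep(1, ncol(x))
         else factors$tmm_factor[match(colnames(x), factors$sample_id)]
  if (anyNA(fac)) stop("normalization factors missing for some samples", call. = FALSE)
  eff_lib <- lib * fac
  if (nrow(design) != ncol(x)) stop("design rows must match samples", call. = FALSE)
  if (qr(design)$rank < ncol(design))
    stop("design matrix is not full rank", call. = FALSE)
  if (ncol(x) - ncol(design) < 1)
    stop("fewer than 1 residual degree of freedom", call. = FALSE)

  log_cpm <- t(log2(t(x + 0.5) / (eff_lib + 1) * 1e6))
  fit <- .fit_lm_genes(log_cpm, design, weights = NULL)
  sy <- sqrt(sqrt(fit$sigma2))                   # sd^(1/2)
  # average log2 count size: mean log-cpm put back on the count scale
  sx <- rowMeans(log_cpm) + mean(log2(eff_lib + 1)) - log2(1e6)
  ok <- is.finite(sx) & is.finite(sy)
  lo <- stats::lowess(sx[ok], sy[ok], f = span)
  # evaluate the trend at each observation's fitted log2 count
  fitted_cpm <- 2^fit$fitted
  fitted_count <- t(t(fitted_cpm) * (eff_lib + 1)) / 1e6
  fitted_logcount <- log2(fitted_count)
  trend_val <- stats::approx(lo$x, lo$y, xout = as.vector(fitted_logcount),
                             rule = 2, ties = "ordered")$y
  w <- matrix(trend_val^-4, nrow = nrow(x), dimnames = dimnames(x))
  if (any(!is.finite(w)) || any(w <= 0))
    stop("non-positive precision weights produced", call. = FALSE)
  list(log_cpm = log_cpm, weights = w, trend = lo)
}

# gene-wise (weighted) least squares; returns coefficients, fitted values,
# residual variance and df, and unscaled standard errors of the coefficients
.fit_lm_genes <- function(y, design, weights = NULL) {
  ng <- nrow(y); p <- ncol(design); n <- ncol(y)
  df_resid <- n - p
  coefs <- matrix(NA_real_, ng, p, dimnames = list(rownames(y), colnames(design)))
  stdev_unscaled <- coefs
  fitted <- matrix(NA_real_, ng, n, dimnames = dimnames(y))
  sigma2 <- numeric(ng)
  for (g in seq_len(ng)) {
    w <- if (is.null(weights)) rep(1, n) else weights[g, ]
    fit <- stats::lm.wfit(design, y[g, ], w)
    coefs[g, ] <- fit$coefficients
    fitted[g, ] <- y[g, ] - fit$residuals
    sigma2[g] <- sum(w * fit$residuals^2) / df_resid
    xtx_inv <- chol2inv(chol(crossprod(design * sqrt(w))))
    stdev_unscaled[g, ] <- sqrt(diag(xtx_inv))
  }
  list(coefficients = coefs, fitted = fitted, sigma2 = sigma2,
       df_residual = df_resid, stdev_unscaled = stdev_unscaled)
}

#' Gene-wise weighted linear model fit
#'
#' Weighted least squares per gene under a shared design matrix; in the
#' contamination analysis the first non-intercept coefficient is the log2 fold
#' change of the high- versus low-contamination group.
#'
#' @param log_cpm genes x samples matrix of log2 expression.
#' @param weights matching matrix of positive observation weights (NULL for
#'   unit weights).
#' @param design numeric design matrix (samples x coefficients), full rank.
#' @return list: `coefficients` (genes x p), `sigma2` (residual variance),
#'   `df_residual`, `stdev_unscaled` (genes x p unscaled coefficient SEs),
#'   `fitted`.
#' @export
fit_weighted_lm <- function(log_cpm, weights, design) {
  if (!is.null(weights) && !identical(dim(weights), dim(log_cpm)))
    stop("weights must match log_cpm dimensions", call. = FALSE)
  if (nrow(design) != ncol(log_cpm))
    stop("design rows must match samples", call. = FALSE)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    aliased <- colnames(design)[setdiff(seq_len(ncol(design)),
                                        qrd$pivot[seq_len(qrd$rank)])]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  if (ncol(log_cpm) - ncol(design) < 1)
    stop("fewer than 1 residual degree of freedom", call. = FALSE)
  .fit_lm_genes(log_cpm, design, weights)
}

#' Empirical-Bayes variance moderation and moderated t-statistics
#'
#' Gene-wise residual variances are shrunk toward a global prior estimated by
#' moment matching on the log scale: with `z = log(s^2)`, `e = z -
#' digamma(df/2) + log(df/2)` has mean `log(s0^2)` and excess variance
#' `trigamma(d0/2)` under a scaled inverse-chi-square prior, so `d0` solves a
#' trigamma inversion and `s0^2` follows in closed form. The posterior variance
#' is `(d0 s0^2 + df s^2) / (d0 + df)`; moderated t uses it in place of `s^2`
#' with `d0 + df` degrees of freedom. When the variances carry no excess
#' spread, `d0` is infinite and every posterior variance equals `s0^2`.
#'
#' @param sigma2 per-gene residual variances.
#' @param df residual degrees of freedom (scalar or per-gene).
#' @param coefficients optional per-gene coefficient values.
#' @param stdev_unscaled matching unscaled standard errors (required with
#'   `coefficients`).
#' @return list: `s2_post`, `df_prior` (d0), `s2_prior` (s0^2), and — when
#'   coefficients are supplied — `t` (moderated), `p_value` (two-sided,
#'   df + d0), `df_total`.
#' @export
moderate_variances <- function(sigma2, df, coefficients = NULL,
                               stdev_unscaled = NULL) {
  if (length(df) == 1) df <- rep(df, length(sigma2))
  ok <- sigma2 > 0 & df > 0
  if (sum(ok) < 2) stop("need >=2 genes with positive variance and df", call. = FALSE)
  z <- log(sigma2[ok])
  if (stats::var(z) == 0) {
    # literally constant variances carry no information about prior spread:
    # the posterior equals the observed variance exactly
    df_prior <- Inf
    s2_prior <- sigma2[ok][1]
  } else {
    e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
    e_mean <- mean(e)
    excess <- stats::var(e) - mean(trigamma(df[ok] / 2))
    if (is.na(excess) || excess <= 0) {
      df_prior <- Inf
      s2_prior <- exp(e_mean)
    } else {
      df_prior <- 2 * .trigamma_inverse(excess)
      s2_prior <- exp(e_mean + digamma(df_prior / 2) - log(df_prior / 2))
    }
  }
  s2_post <- if (is.infinite(df_prior)) rep(s2_prior, length(sigma2))
             else (df_prior * s2_prior + df * sigma2) / (df_prior + df)
  out <- list(s2_post = s2_post, df_prior = df_prior, s2_prior = s2_prior)
  if (!is.null(coefficients)) {
    if (is.null(stdev_unscaled)) stop("stdev_unscaled required", call. = FALSE)
    tmod <- coefficients / (stdev_unscaled * sqrt(s2_post))
    df_total <- df + df_prior
    out$t <- tmod
    out$df_total <- df_total
    out$p_value <- 2 * stats::pt(-abs(tmod), df_total)
  }
  out
}

# Newton inversion of trigamma on (0, Inf); x > 0
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}
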