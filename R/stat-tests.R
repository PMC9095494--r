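#' One-way ANOVA on a numeric vector by group
#'
#' Classic fixed-effects one-way ANOVA: `F = MSB / MSW` with degrees of freedom
#' `(k - 1, N - k)` and an upper-tail F p-value. Groups with no observations
#' are dropped. The result is NA-flagged (rather than an error) whenever the
#' test is undefined: a single group, no residual degrees of freedom, or zero
#' variance both within and between groups. NA-flagged profiles are later
#' excluded from the multiple-testing family, mirroring how degenerate
#' expression profiles are dropped from a survey.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @return list of class `cp_test`: `statistic`, `df` (length 2), `p_value`,
#'   `method = "one_way_anova"`; all NA when undefined.
#' @export
one_way_anova <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  na_result <- structure(list(statistic = NA_real_, df = c(NA_real_, NA_real_),
                              p_value = NA_real_, method = "one_way_anova"),
                         class = "cp_test")
  k <- length(unique(groups)); n <- length(values)
  if (n == 0 || k < 2 || n - k < 1) return(na_result)
  grand <- mean(values)
  gmeans <- tapply(values, groups, mean)
  gsizes <- tapply(values, groups, length)
  ssb <- sum(gsizes * (gmeans - grand)^2)
  ssw <- sum((values - gmeans[groups])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  if (msw == 0) {
    if (msb == 0) return(na_result)              # all values identical
    return(structure(list(statistic = Inf, df = c(k - 1, n - k),
                          p_value = 0, method = "one_way_anova"),
                     class = "cp_test"))
  }
  f <- msb / msw
  structure(list(statistic = f, df = c(k - 1, n - k),
                 p_value = stats::pf(f, k - 1, n - k, lower.tail = FALSE),
                 method = "one_way_anova"), class = "cp_test")
}

#' @export
print.cp_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, df = %s, p = %s\n", x$method,
              format(x$statistic), paste(format(x$df), collapse = ", "),
              format(x$p_value)))
  invisible(x)
}

#' Bonferroni correction
#'
#' `adjusted = min(1, p * m)` where `m` is the number of non-missing p-values
#' in the family; NA entries propagate and do not count toward `m`.
#'
#' @param p_values numeric vector of p-values (NAs allowed).
#' @return adjusted p-values, same length and order.
#' @export
bonferroni <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- sum(ok)
  out <- rep(NA_real_, length(p_values))
  if (m > 0) out[ok] <- pmin(1, p_values[ok] * m)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-controlling adjustment: with order statistics `p_(1) <= ... <=
#' p_(m)`, `adj_(i) = min_{j >= i} min(1, m * p_(j) / j)`. NA entries propagate
#' and are excluded from `m`.
#'
#' @param p_values numeric vector of p-values.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p_values))
  p <- p_values[ok]
  m <- length(p)
  if (m > 0) {
    o <- order(p, decreasing = TRUE)
    adj <- pmin(1, cummin(m / seq(m, 1) * p[o]))
    out[ok][o] <- adj
  }
  out
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic:
#' `H = [(12 / (N(N+1))) * sum(R_j^2 / n_j) - 3(N+1)] / (1 - sum(t^3 - t) /
#' (N^3 - N))` with a chi-square p-value on `k - 1` degrees of freedom. Used
#' to compare marker log2-expression distributions across (heavily tied) age
#' bins.
#'
#' @param values numeric vector.
#' @param bins group labels, same length.
#' @return `cp_test` with `statistic` (H), `df = k - 1`, `p_value`; NA-flagged
#'   when all values are identical or fewer than 2 bins remain.
#' @export
kruskal_wallis <- function(values, bins) {
  keep <- !is.na(values) & !is.na(bins)
  values <- values[keep]; bins <- as.character(bins[keep])
  na_result <- structure(list(statistic = NA_real_, df = NA_real_,
                              p_value = NA_real_, method = "kruskal_wallis"),
                         class = "cp_test")
  k <- length(unique(bins)); n <- length(values)
  if (k < 2 || n < 2) return(na_result)
  r <- rank(values)
  rsum <- tapply(r, bins, sum)
  nj <- tapply(r, bins, length)
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / nj) - 3 * (n + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (correction == 0) return(na_result)         # all values tied
  h <- h / correction
  structure(list(statistic = h, df = k - 1,
                 p_value = stats::pchisq(h, k - 1, lower.tail = FALSE),
                 method = "kruskal_wallis"), class = "cp_test")
}

#' Hypergeometric gene-set over-representation
#'
#' For each gene set, the upper-tail hypergeometric probability of observing
#' at least the seen overlap between the query list and the set, both first
#' intersected with the universe. P-values are BH-adjusted across sets.
#'
#' @param de_list character vector of query gene ids (e.g. upregulated genes);
#'   must be contained in the universe.
#' @param sets a [gene_sets()] collection.
#' @param universe character vector of background gene ids (defaults to
#'   `sets$universe`).
#' @return data.frame: set_name, overlap, set_size, list_size, universe_size,
#'   p_value, adjusted_p.
#' @export
hypergeometric_enrichment <- function(de_list, sets, universe = sets$universe) {
  if (is.null(universe) || !length(universe))
    stop("an enrichment universe is required", call. = FALSE)
  universe <- unique(universe)
  stray <- setdiff(de_list, universe)
  if (length(stray))
    stop("query gene(s) outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  de_list <- unique(de_list)
  n_univ <- length(universe)
  n_list <- length(de_list)
  res <- do.call(rbind, lapply(names(sets$sets), function(nm) {
    s <- intersect(sets$sets[[nm]], universe)
    ov <- length(intersect(s, de_list))
    p <- if (ov == 0) 1 else
      stats::phyper(ov - 1, length(s), n_univ - length(s), n_list,
                    lower.tail = FALSE)
    data.frame(set_name = nm, overlap = ov, set_size = length(s),
               list_size = n_list, universe_size = n_univ, p_value = p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(res)) {
    res <- data.frame(set_name = character(), overlap = integer(),
                      set_size = integer(), list_size = integer(),
                      universe_size = integer(), p_value = double(),
                      adjusted_p = double(), stringsAsFactors = FALSE)
    return(res)
  }
  res$adjusted_p <- bh_adjust(res$p_value)
  res[order(res$p_value), , drop = FALSE]
}
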