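#' Marker log2-expression thresholds for contamination grouping
#'
#' Samples below `low_cut` log2 marker expression are labelled "low
#' contamination", above `high_cut` "high", and in between "unassigned" (and
#' excluded from the comparison). The TTR defaults 3.32/5.32 correspond to
#' roughly 10 and 40 TPM; the FOLR1 convention is -1/+1.
#'
#' @param marker marker gene id.
#' @param low_cut log2 expression below which a sample is low-contamination.
#' @param high_cut log2 expression above which a sample is high-contamination.
#' @return a `cp_thresholds` list.
#' @export
contamination_thresholds <- function(marker = "TTR", low_cut = 3.32,
                                     high_cut = 5.32) {
  if (!(low_cut < high_cut)) stop("low_cut must be < high_cut", call. = FALSE)
  structure(list(marker = marker, low_cut = low_cut, high_cut = high_cut),
            class = "cp_thresholds")
}

#' Default FOLR1 thresholds
#' @return a [contamination_thresholds()] for FOLR1 (-1 / +1).
#' @export
folr1_thresholds <- function() contamination_thresholds("FOLR1", -1, 1)

#' Assign samples to contamination groups by marker expression
#'
#' @param log2_vals named per-sample log2 marker expression (finite; use
#'   [log2_expression()]).
#' @param thr a [contamination_thresholds()].
#' @return data.frame: sample_id, label (low/high/unassigned), marker_log2.
#' @export
assign_groups <- function(log2_vals, thr = contamination_thresholds()) {
  if (any(!is.finite(log2_vals)))
    stop("log2 marker values must be finite", call. = FALSE)
  label <- ifelse(log2_vals < thr$low_cut, "low",
                  ifelse(log2_vals > thr$high_cut, "high", "unassigned"))
  data.frame(sample_id = names(log2_vals), label = label,
             marker_log2 = as.numeric(log2_vals),
             row.names = NULL, stringsAsFactors = FALSE)
}

# design matrix: intercept, labelhigh, then covariates. age_bin is encoded as
# an ordinal integer by default (bins are ordered, few levels)
.de_design <- function(meta, labels, covariates, age_encoding = "ordinal") {
  label <- factor(labels, levels = c("low", "high"))
  df <- data.frame(labelhigh = as.integer(label == "high"))
  for (cv in covariates) {
    if (!cv %in% names(meta))
      stop("covariate '", cv, "' missing from metadata", call. = FALSE)
    v <- meta[[cv]]
    if (length(unique(v)) < 2) {
      warning("covariate '", cv, "' is constant in the analyzed samples; dropped",
              call. = FALSE)
      next
    }
    if (cv == "age_bin" && age_encoding == "ordinal") {
      df[[cv]] <- as.integer(factor(v, levels = sort(unique(v))))
    } else if (is.numeric(v)) {
      df[[cv]] <- v
    } else {
      f <- factor(v)
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, levels(f)[-1])
      df <- cbind(df, mm)
    }
  }
  as.matrix(cbind(intercept = 1, df))
}

#' Differential-expression configuration
#'
#' @param min_cpm CPM a gene must exceed (strictly) to count as expressed.
#' @param min_samples samples above `min_cpm` required to keep a gene; also the
#'   minimum size of each contamination group.
#' @param fdr_cut BH-adjusted p cutoff for a DE call.
#' @param lfc_cut absolute log2 fold-change cutoff for a DE call.
#' @param covariates metadata fields adjusted for in the linear model.
#' @param age_encoding `"ordinal"` (integer per ordered bin) or `"categorical"`.
#' @param voom_span lowess span of the mean-variance trend.
#' @return a `cp_deconfig` list.
#' @export
de_config <- function(min_cpm = 2, min_samples = 3, fdr_cut = 0.05,
                      lfc_cut = 1.0, covariates = c("sex", "age_bin"),
                      age_encoding = c("ordinal", "categorical"),
                      voom_span = 0.5) {
  age_encoding <- match.arg(age_encoding)
  if (min_cpm <= 0) stop("min_cpm must be > 0", call. = FALSE)
  if (min_samples < 1) stop("min_samples must be >= 1", call. = FALSE)
  if (fdr_cut <= 0 || fdr_cut >= 1) stop("fdr_cut must lie in (0, 1)", call. = FALSE)
  structure(list(min_cpm = min_cpm, min_samples = min_samples,
                 fdr_cut = fdr_cut, lfc_cut = lfc_cut, covariates = covariates,
                 age_encoding = age_encoding, voom_span = voom_span),
            class = "cp_deconfig")
}

#' Differential expression between contamination groups
#'
#' The confirmation stage of the contamination screen: genes differentially
#' expressed between marker-high and marker-low samples. Composes CPM
#' conversion, the expressed-gene filter, TMM scaling factors, log-CPM with
#' mean-variance precision weights, gene-wise weighted linear models with the
#' contamination coefficient plus covariates, empirical-Bayes variance
#' moderation, BH adjustment, and the DE call (`adj_p < fdr_cut` and
#' `|log2 FC| > lfc_cut`). Unassigned samples are excluded.
#'
#' @param counts `cp_expr` of raw counts or TPM (TPM is run through the same
#'   CPM/TMM path, matching the survey protocol for depth-normalized inputs).
#' @param meta sample metadata (sample_id, group, plus covariate columns).
#' @param labels data.frame from [assign_groups()].
#' @param cfg a [de_config()].
#' @param moderation empirical-Bayes variance moderation (disable to get
#'   ordinary per-gene weighted-LS t-tests).
#' @param use_voom_weights precision weights from the mean-variance trend
#'   (disable for unit weights).
#' @return object of class `cp_de`: list with `table` (data.frame: gene_id,
#'   log2_fc, avg_expr, t, p, adj_p, call), `n_samples` (named low/high),
#'   `factors`, `df_prior`, `s2_prior`, `config`, `design`.
#' @export
contamination_de <- function(counts, meta, labels, cfg = de_config(),
                             moderation = TRUE, use_voom_weights = TRUE) {
  meta <- validate_metadata(meta)
  keep_s <- labels$sample_id[labels$label %in% c("low", "high")]
  keep_s <- intersect(colnames(counts), keep_s)
  lab <- labels$label[match(keep_s, labels$sample_id)]
  n_low <- sum(lab == "low"); n_high <- sum(lab == "high")
  if (n_low < cfg$min_samples || n_high < cfg$min_samples)
    stop("contamination group below minimum size (low = ", n_low,
         ", high = ", n_high, ", minimum ", cfg$min_samples, ")", call. = FALSE)
  x <- counts[, keep_s]
  m <- meta[match(keep_s, meta$sample_id), , drop = FALSE]

  cp <- cpm(x)
  mask <- filter_by_cpm(cp, cfg$min_cpm, cfg$min_samples)
  xf <- x[mask, , drop = FALSE]
  if (nrow(xf) < 2) stop("fewer than 2 genes pass the expression filter",
                         call. = FALSE)
  fac <- tmm_factors(xf)
  design <- .de_design(m, lab, cfg$covariates, cfg$age_encoding)
  v <- voom_transform(xf, fac, design, span = cfg$voom_span)
  w <- if (use_voom_weights) v$weights else NULL
  fit <- fit_weighted_lm(v$log_cpm, w, design)

  coef_i <- match("labelhigh", colnames(design))
  b <- fit$coefficients[, coef_i]
  se_u <- fit$stdev_unscaled[, coef_i]
  if (moderation) {
    mod <- moderate_variances(fit$sigma2, fit$df_residual, b, se_u)
    tstat <- mod$t; pval <- mod$p_value
    df_prior <- mod$df_prior; s2_prior <- mod$s2_prior
  } else {
    tstat <- b / (se_u * sqrt(fit$sigma2))
    pval <- 2 * stats::pt(-abs(tstat), fit$df_residual)
    df_prior <- 0; s2_prior <- NA_real_
  }
  adj <- bh_adjust(pval)
  call <- ifelse(adj < cfg$fdr_cut & b > cfg$lfc_cut, "up",
                 ifelse(adj < cfg$fdr_cut & b < -cfg$lfc_cut, "down", "ns"))
  tab <- data.frame(gene_id = rownames(xf), log2_fc = b,
                    avg_expr = rowMeans(v$log_cpm), t = tstat, p = pval,
                    adj_p = adj, call = call,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, n_samples = c(low = n_low, high = n_high),
                 n_genes_in = nrow(counts), n_genes_tested = nrow(xf),
                 factors = fac, df_prior = df_prior, s2_prior = s2_prior,
                 config = cfg, design = design), class = "cp_de")
}

#' @export
print.cp_de <- function(x, ...) {
  cat(sprintf("Contamination DE: %d low vs %d high samples, %d/%d genes tested\n",
              x$n_samples["low"], x$n_samples["high"],
              x$n_genes_tested, x$n_genes_in))
  cat(sprintf("  calls at adj p < %g, |log2 FC| > %g: %d up, %d down\n",
              x$config$fdr_cut, x$config$lfc_cut,
              sum(x$table$call == "up"), sum(x$table$call == "down")))
  invisible(x)
}

#' @export
summary.cp_de <- function(object, n = 10, ...) {
  print(object)
  tab <- object$table[order(object$table$p), , drop = FALSE]
  cat("\nTop genes:\n")
  print(utils::head(tab, n), row.names = FALSE, digits = 4)
  invisible(tab)
}

#' @export
coef.cp_de <- function(object, ...) {
  stats::setNames(object$table$log2_fc, object$table$gene_id)
}

#' Volcano plot of a contamination DE fit
#' @param x a `cp_de` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cp_de <- function(x, ...) {
  tab <- x$table
  col <- ifelse(tab$call == "up", "red3",
                ifelse(tab$call == "down", "blue3", "grey60"))
  graphics::plot(tab$log2_fc, -log10(tab$p), col = col, pch = 16, cex = 0.5,
                 xlab = "log2 fold change (high vs low contamination)",
                 ylab = "-log10 p", ...)
  graphics::abline(v = c(-x$config$lfc_cut, x$config$lfc_cut), lty = 2)
  invisible(NULL)
}

#' Genes called differentially expressed
#' @param fit a `cp_de` object.
#' @param direction `"up"`, `"down"` or `"both"`.
#' @return character vector of gene ids.
#' @export
de_genes <- function(fit, direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  keep <- if (direction == "both") fit$table$call != "ns"
          else fit$table$call == direction
  fit$table$gene_id[keep]
}

#' Sex-stratified contamination DE
#'
#' Reruns [contamination_de()] within each sex (covariates minus sex). Strata
#' in which either contamination group falls below `min_per_group` are skipped
#' with a warning rather than fitted underpowered.
#'
#' @inheritParams contamination_de
#' @param min_per_group minimum low/high group size within a stratum.
#' @return named list of `cp_de` fits (skipped strata absent).
#' @export
run_sex_stratified <- function(counts, meta, labels, cfg = de_config(),
                               min_per_group = 3) {
  meta <- validate_metadata(meta)
  if (!"sex" %in% names(meta)) stop("metadata has no sex column", call. = FALSE)
  cfg2 <- cfg
  cfg2$covariates <- setdiff(cfg$covariates, "sex")
  out <- list()
  for (sx in unique(meta$sex)) {
    sids <- meta$sample_id[meta$sex == sx]
    lab_s <- labels[labels$sample_id %in% sids, , drop = FALSE]
    nlo <- sum(lab_s$label == "low"); nhi <- sum(lab_s$label == "high")
    if (nlo < min_per_group || nhi < min_per_group) {
      warning("sex stratum '", sx, "' skipped: group sizes low = ", nlo,
              ", high = ", nhi, " below minimum ", min_per_group, call. = FALSE)
      next
    }
    out[[sx]] <- contamination_de(counts[, intersect(colnames(counts), sids)],
                                  meta[meta$sex == sx, , drop = FALSE],
                                  lab_s, cfg2)
  }
  out
}
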