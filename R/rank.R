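#' Remove mitochondrial genes
#'
#' Mitochondrial transcripts are so highly expressed that they compress the
#' percentile ranks of everything else, so they are removed before ranking.
#' Recognition is by gene-symbol prefix, case-insensitive by default (`"MT-"`
#' matches human `MT-CO1` and mouse `mt-Co1`).
#'
#' @param m a `cp_expr` matrix with gene symbols as rownames.
#' @param pattern prefix identifying mitochondrial genes.
#' @param ignore_case match the prefix case-insensitively.
#' @return the matrix without matching genes; the number removed is reported
#'   via `message()`.
#' @export
remove_mt_genes <- function(m, pattern = "MT-", ignore_case = TRUE) {
  ids <- rownames(m)
  if (ignore_case) hit <- startsWith(toupper(ids), toupper(pattern))
  else hit <- startsWith(ids, pattern)
  message("removed ", sum(hit), " mitochondrial gene(s), ", sum(!hit), " remaining")
  m[!hit, , drop = FALSE]
}

#' Within-sample percentile ranks
#'
#' Places each sample's expression values on a 0-100 percentile scale using
#' the midrank convention: `rank(x) = 100 * (#\{values < x\} + 0.5 *
#' #\{values = x\}) / n_genes`. Ranks depend only on within-sample ordering,
#' so they are invariant to depth and to any strictly increasing per-sample
#' transform; the mean rank within a sample is exactly 50.
#'
#' @param m `cp_expr` with unit counts, TPM or CPM.
#' @return a `cp_ranked` object: genes x samples matrix of percentiles, with
#'   the gene/sample ids of `m`.
#' @export
percentile_rank <- function(m) {
  if (expr_unit(m) == "log2")
    stop("percentile_rank expects counts/TPM/CPM input", call. = FALSE)
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty expression matrix", call. = FALSE)
  n <- nrow(m)
  # base rank() with ties.method="average" is (#less + (#equal+1)/2); shift to
  # the midrank count convention (#less + #equal/2)
  ranks <- apply(unclass(m), 2, function(x) 100 * (rank(x) - 0.5) / n)
  if (n == 1L) ranks <- matrix(ranks, nrow = 1L, dimnames = dimnames(m))
  structure(ranks, class = c("cp_ranked", "matrix", "array"))
}

#' @export
print.cp_ranked <- function(x, ...) {
  cat(sprintf("cp_ranked: %d genes x %d samples (percentile ranks 0-100)\n",
              nrow(x), ncol(x)))
  k <- min(5L, nrow(x)); m <- min(5L, ncol(x))
  print(round(unclass(x)[seq_len(k), seq_len(m), drop = FALSE], 2))
  invisible(x)
}

#' Marker rank summaries per stratum
#'
#' Mean/min/max percentile rank of each marker gene within each level of a
#' metadata field (e.g. brain region, experimental group).
#'
#' @param r a `cp_ranked` matrix from [percentile_rank()].
#' @param panel a [marker_panel()]; all panel genes must be present.
#' @param meta sample metadata data.frame (`sample_id` plus the stratifier).
#' @param stratify_by metadata column to stratify on; `NULL` summarizes over
#'   all samples as one stratum `"all"`.
#' @return data.frame: marker, stratum, n, mean_rank, min_rank, max_rank.
#' @export
marker_rank_summary <- function(r, panel, meta = NULL, stratify_by = NULL) {
  missing <- setdiff(panel$gene_ids, rownames(r))
  if (length(missing))
    stop("marker(s) absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(stratify_by)) {
    strata <- rep("all", ncol(r))
  } else {
    if (is.null(meta)) stop("metadata required when stratifying", call. = FALSE)
    meta <- validate_metadata(meta)
    if (!stratify_by %in% names(meta))
      stop("no metadata column '", stratify_by, "'", call. = FALSE)
    idx <- match(colnames(r), meta$sample_id)
    if (anyNA(idx)) stop("ranked samples missing from metadata", call. = FALSE)
    strata <- as.character(meta[[stratify_by]][idx])
  }
  out <- do.call(rbind, lapply(panel$gene_ids, function(g) {
    do.call(rbind, lapply(unique(strata), function(s) {
      v <- unclass(r)[g, strata == s]
      data.frame(marker = g, stratum = s, n = length(v),
                 mean_rank = mean(v), min_rank = min(v), max_rank = max(v),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

# offset added before log2 so zero-expression samples get a finite value
# (-10 for TPM 0) that sits decisively below every low-contamination cutoff
.LOG2_EPS <- 2^-10

#' Per-sample log2 expression of one gene
#'
#' `log2(TPM + 2^-10)`: the small offset keeps zero-TPM samples finite (exactly
#' -10) without ever lifting a genuinely low sample across the contamination
#' thresholds used downstream.
#'
#' @param m `cp_expr` with unit TPM (or CPM).
#' @param gene gene id.
#' @return named numeric vector of log2 values, one per sample.
#' @export
log2_expression <- function(m, gene) {
  if (!expr_unit(m) %in% c("TPM", "CPM"))
    stop("log2_expression expects TPM or CPM input", call. = FALSE)
  if (!gene %in% rownames(m))
    stop("gene '", gene, "' absent from matrix", call. = FALSE)
  v <- log2(unclass(m)[gene, ] + .LOG2_EPS)
  stats::setNames(v, colnames(m))
}
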