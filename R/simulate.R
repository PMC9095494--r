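#' Configuration for the tissue/contaminant mixture simulator
#'
#' Describes a bulk RNA-seq experiment in which each sample's RNA is a mixture
#' of a target tissue and a contaminating tissue (the choroid plexus analogue)
#' with per-sample contamination fraction `f`. Marker genes are expressed
#' `marker_fold` times higher in the contaminant than in the target tissue, so
#' even small `f` moves them by orders of magnitude; all other genes have equal
#' means in both tissues.
#'
#' Contamination modes:
#' \describe{
#'   \item{none}{every sample has `f = 0`.}
#'   \item{random}{each sample is clean with probability `clean_probability`,
#'     otherwise `f ~ Beta(f_shape1, f_shape2)`, irrespective of group.}
#'   \item{group_biased}{contamination probability is scaled per group by
#'     `group_bias` (default: first group 0 — clean; remaining groups 1 —
#'     every sample contaminated with `f ~ Beta`).}
#' }
#'
#' @param n_genes total number of genes (markers included).
#' @param n_marker_genes number of contaminant marker genes; the first three
#'   are named TTR, FOLR1, PRLR.
#' @param samples_per_group named integer vector, samples per experimental group.
#' @param marker_fold contaminant/tissue mean ratio for marker genes (> 1).
#' @param contamination_mode one of `"none"`, `"random"`, `"group_biased"`.
#' @param clean_probability probability a sample is contamination-free in
#'   `random` mode.
#' @param f_shape1,f_shape2 Beta parameters of the contamination fraction for
#'   contaminated samples (default Beta(2, 18), mean 0.1).
#' @param group_bias named numeric vector of per-group multipliers on the
#'   contamination probability (`group_biased` mode only); defaults to 0 for
#'   the first group and 1 for the rest.
#' @param libsize_range min/max library size; per-sample sizes drawn uniformly.
#' @param dispersion negative-binomial dispersion (constant across genes; > 0).
#' @param marker_base_mean mean expression of marker genes in clean target
#'   tissue (low: markers are near-silent outside the contaminant).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters for non-marker
#'   baseline means (sdlog 2 spans several orders of magnitude of expression).
#' @param seed integer seed; identical config + seed gives identical output.
#' @return a `cp_simconfig` list.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_marker_genes = 3L,
                       samples_per_group = c(control = 6L, case = 6L),
                       marker_fold = 1e4,
                       contamination_mode = c("none", "random", "group_biased"),
                       clean_probability = 0.5,
                       f_shape1 = 2, f_shape2 = 18,
                       group_bias = NULL,
                       libsize_range = c(8e5, 1.2e6),
                       dispersion = 0.1,
                       marker_base_mean = 1,
                       baseline_meanlog = 3, baseline_sdlog = 2,
                       seed = 1L) {
  contamination_mode <- match.arg(contamination_mode)
  if (is.null(names(samples_per_group)) || any(!nzchar(names(samples_per_group))))
    stop("samples_per_group must be a named vector", call. = FALSE)
  if (any(samples_per_group < 1))
    stop("every group needs >=1 sample", call. = FALSE)
  if (n_marker_genes >= n_genes)
    stop("n_marker_genes must be < n_genes", call. = FALSE)
  if (marker_fold <= 1) stop("marker_fold must be > 1", call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  if (clean_probability < 0 || clean_probability > 1)
    stop("clean_probability must lie in [0, 1]", call. = FALSE)
  if (length(libsize_range) != 2 || libsize_range[1] > libsize_range[2] ||
      libsize_range[1] <= 0)
    stop("libsize_range must be positive (min, max)", call. = FALSE)
  if (is.null(group_bias)) {
    group_bias <- c(0, rep(1, length(samples_per_group) - 1L))
    names(group_bias) <- names(samples_per_group)
  }
  if (!all(names(samples_per_group) %in% names(group_bias)))
    stop("group_bias must cover every group", call. = FALSE)
  structure(list(
    n_genes = as.integer(n_genes), n_marker_genes = as.integer(n_marker_genes),
    samples_per_group = samples_per_group, marker_fold = marker_fold,
    contamination_mode = contamination_mode,
    clean_probability = clean_probability,
    f_shape1 = f_shape1, f_shape2 = f_shape2, group_bias = group_bias,
    libsize_range = libsize_range, dispersion = dispersion,
    marker_base_mean = marker_base_mean,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    seed = as.integer(seed)), class = "cp_simconfig")
}

.marker_ids <- function(n) {
  canonical <- c("TTR", "FOLR1", "PRLR")
  if (n <= 3L) canonical[seq_len(n)]
  else c(canonical, sprintf("CPMARK%02d", seq_len(n - 3L) + 3L))
}

# deterministic per-sample substream seed (counter-based): adding samples
# never perturbs earlier ones; kept below 2^31
.substream_seed <- function(seed, i) {
  (abs(seed) %% 1000003L) * 2011L + 7919L * i
}

#' Gene-level mixture means of a simulation config
#'
#' Expected (pre-depth) expression per gene at contamination fraction `f`:
#' `mu(f) = (1 - f) * mu_tissue + f * mu_contaminant`. Exposed so tests and
#' downstream checks can compute expected marker abundance analytically.
#'
#' @param config a [sim_config()].
#' @return list with `gene_ids`, `mu_tissue`, `mu_contaminant`.
#' @export
sim_gene_means <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes; nm <- config$n_marker_genes
  gene_ids <- c(.marker_ids(nm), sprintf("GENE%05d", seq_len(n - nm)))
  mu_tissue <- c(rep(config$marker_base_mean, nm),
                 stats::rlnorm(n - nm, config$baseline_meanlog, config$baseline_sdlog))
  mu_cont <- mu_tissue
  mu_cont[seq_len(nm)] <- mu_tissue[seq_len(nm)] * config$marker_fold
  list(gene_ids = gene_ids, mu_tissue = mu_tissue, mu_contaminant = mu_cont)
}

#' Simulate a tissue/contaminant mixture RNA-seq dataset
#'
#' Counts for gene g in sample s are negative binomial with mean
#' `mu_gs * L_s / sum_g(mu_gs)` where `mu_gs = (1 - f_s) mu_g^tissue +
#' f_s mu_g^contaminant`, `L_s` the library size and the configured constant
#' dispersion. Sex and age bin are assigned uniformly at random per sample.
#'
#' @param config a [sim_config()].
#' @return list with elements
#'   \describe{
#'     \item{counts}{`cp_expr` counts matrix.}
#'     \item{metadata}{data.frame: sample_id, group, sex, age_bin.}
#'     \item{truth}{data.frame: sample_id, f (true contamination fraction), group.}
#'     \item{markers}{[marker_panel()] of the simulated contaminant markers.}
#'   }
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "cp_simconfig"))
  gm <- sim_gene_means(config)
  groups <- rep(names(config$samples_per_group), times = config$samples_per_group)
  ns <- length(groups)
  sample_ids <- sprintf("S%03d", seq_len(ns))
  age_bins <- c("70-74", "75-79", "80-84", "85-89")

  counts <- matrix(0, nrow = config$n_genes, ncol = ns,
                   dimnames = list(gm$gene_ids, sample_ids))
  f <- numeric(ns); sex <- character(ns); age <- character(ns)
  for (i in seq_len(ns)) {
    set.seed(.substream_seed(config$seed, i))
    sex[i] <- sample(c("female", "male"), 1L)
    age[i] <- sample(age_bins, 1L)
    p_cont <- switch(config$contamination_mode,
      none = 0,
      random = 1 - config$clean_probability,
      group_biased = min(1, max(0, config$group_bias[[groups[i]]])))
    f[i] <- if (stats::runif(1) < p_cont)
      stats::rbeta(1, config$f_shape1, config$f_shape2) else 0
    lib <- stats::runif(1, config$libsize_range[1], config$libsize_range[2])
    mu <- (1 - f[i]) * gm$mu_tissue + f[i] * gm$mu_contaminant
    counts[, i] <- stats::rnbinom(config$n_genes, mu = mu * lib / sum(mu),
                                  size = 1 / config$dispersion)
  }
  list(
    counts = expression_matrix(counts, "counts"),
    metadata = data.frame(sample_id = sample_ids, group = groups,
                          sex = sex, age_bin = age, stringsAsFactors = FALSE),
    truth = data.frame(sample_id = sample_ids, f = f, group = groups,
                       stringsAsFactors = FALSE),
    markers = marker_panel(gm$gene_ids[seq_len(config$n_marker_genes)],
                           name = "simulated_contaminant"))
}

#' Convert counts to transcripts per million
#'
#' Per sample: `rate_g = count_g / length_g`, `TPM_g = 1e6 * rate_g / sum(rate)`.
#' Columns sum to 1e6.
#'
#' @param counts `cp_expr` with unit counts.
#' @param gene_lengths named numeric vector of positive gene lengths covering
#'   every gene in `counts`.
#' @return `cp_expr` with unit TPM.
#' @export
tpm_from_counts <- function(counts, gene_lengths) {
  if (expr_unit(counts) != "counts")
    stop("tpm_from_counts expects counts input", call. = FALSE)
  miss <- setdiff(rownames(counts), names(gene_lengths))
  if (length(miss))
    stop("missing gene length(s): ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  len <- gene_lengths[rownames(counts)]
  if (any(len <= 0)) stop("gene lengths must be positive", call. = FALSE)
  rate <- unclass(counts) / len
  cs <- colSums(rate)
  if (any(cs == 0)) stop("sample(s) with zero total rate: ",
                         paste(colnames(counts)[cs == 0], collapse = ", "),
                         call. = FALSE)
  expression_matrix(sweep(rate, 2, cs, "/") * 1e6, "TPM")
}
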