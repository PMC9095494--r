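#' Pipeline run configuration
#'
#' One structured configuration driving the composed contamination screen:
#' simulate (optional) -> rank -> classify -> group -> de -> enrich. Any stage
#' can be toggled off; later stages that depend on a disabled stage's output
#' must be given that input via `paths`.
#'
#' @param out_dir output directory (created if missing).
#' @param stages character vector of stages to run, subset of
#'   `c("simulate", "rank", "classify", "group", "de", "enrich")`.
#' @param sim a [sim_config()] (required when `"simulate"` is on).
#' @param thresholds a [contamination_thresholds()].
#' @param classifier a [classifier_config()].
#' @param de a [de_config()].
#' @param paths named list of input paths for stages whose producer is off:
#'   `expression` (+ `expression_unit`), `metadata`, `markers`, `profiles`,
#'   `gmt`.
#' @param mt_pattern mitochondrial gene prefix removed before ranking.
#' @param seed integer seed recorded in every output header and used for any
#'   stage randomness.
#' @return a `cp_runconfig` list.
#' @export
run_config <- function(out_dir,
                       stages = c("simulate", "rank", "classify", "group",
                                  "de", "enrich"),
                       sim = sim_config(),
                       thresholds = contamination_thresholds(),
                       classifier = classifier_config(),
                       de = de_config(),
                       paths = list(),
                       mt_pattern = "MT-",
                       seed = 1L) {
  structure(list(out_dir = out_dir, stages = stages, sim = sim,
                 thresholds = thresholds, classifier = classifier, de = de,
                 paths = paths, mt_pattern = mt_pattern, seed = as.integer(seed)),
            class = "cp_runconfig")
}

#' Validate a pipeline configuration
#'
#' Collects every problem rather than stopping at the first.
#'
#' @param config a [run_config()].
#' @return character vector of problems (empty when valid).
#' @export
validate_config <- function(config) {
  problems <- character()
  known <- c("simulate", "rank", "classify", "group", "de", "enrich")
  bad <- setdiff(config$stages, known)
  if (length(bad))
    problems <- c(problems, paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  thr <- config$thresholds
  if (!is.null(thr) && !(thr$low_cut < thr$high_cut))
    problems <- c(problems, sprintf("thresholds: low_cut (%g) must be < high_cut (%g)",
                                    thr$low_cut, thr$high_cut))
  de <- config$de
  if (!is.null(de)) {
    if (de$min_cpm <= 0) problems <- c(problems, "de: min_cpm must be > 0")
    if (de$min_samples < 1) problems <- c(problems, "de: min_samples must be >= 1")
    if (de$fdr_cut <= 0 || de$fdr_cut >= 1)
      problems <- c(problems, "de: fdr_cut must lie in (0, 1)")
  }
  needs_expr <- any(c("rank", "group", "de") %in% config$stages) &&
    !"simulate" %in% config$stages
  if (needs_expr && is.null(config$paths$expression))
    problems <- c(problems, "paths: expression input required when simulate stage is off")
  for (nm in names(config$paths)) {
    p <- config$paths[[nm]]
    if (nm != "expression_unit" && is.character(p) && !file.exists(p))
      problems <- c(problems, paste0("paths: ", nm, " file not found: ", p))
  }
  if ("enrich" %in% config$stages && is.null(config$paths$gmt))
    problems <- c(problems, "paths: gmt file required for the enrich stage")
  problems
}

.header_lines <- function(config) {
  cfg_file <- tempfile()
  dput(unclass(config)[setdiff(names(unclass(config)), "out_dir")], cfg_file)
  hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  c(paste0("plexusQC version ", as.character(utils::packageVersion("plexusQC"))),
    paste0("config_hash ", hash),
    paste0("seed ", config$seed))
}

#' Run the composed contamination screen
#'
#' Executes the enabled stages in order, writing every intermediate table into
#' `config$out_dir` (each with a header comment carrying the package version,
#' a config hash, and the seed) and returning a run report. Deterministic for
#' a fixed config and seed.
#'
#' @param config a [run_config()]; validated first, aborting on any problem.
#' @return object of class `cp_report`: per-stage counts, thresholds used,
#'   priority summary, DE call counts, enrichment table, version, seed.
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- .header_lines(config)
  report <- list(version = as.character(utils::packageVersion("plexusQC")),
                 seed = config$seed, stages = config$stages, counts = list())
  expr <- NULL; meta <- NULL; markers <- NULL; truth <- NULL
  labels <- NULL; de_fit <- NULL; ranked <- NULL

  if ("simulate" %in% config$stages) {
    sim <- config$sim
    sim$seed <- config$seed
    ds <- simulate_dataset(sim)
    expr <- ds$counts; meta <- ds$metadata; markers <- ds$markers
    truth <- ds$truth
    write_expression(expr, file.path(config$out_dir, "counts.tsv"), hdr)
    write_table(meta, file.path(config$out_dir, "metadata.tsv"), hdr)
    write_table(truth, file.path(config$out_dir, "truth.tsv"), hdr)
    writeLines(c(paste0("# ", hdr), markers$gene_ids),
               file.path(config$out_dir, "markers.txt"))
    report$counts$simulated <- c(genes = nrow(expr), samples = ncol(expr))
  } else {
    if (!is.null(config$paths$expression)) {
      unit <- config$paths$expression_unit
      if (is.null(unit)) unit <- "counts"
      expr <- read_expression(config$paths$expression, unit)
    }
    if (!is.null(config$paths$metadata))
      meta <- read_metadata(config$paths$metadata, expr)
    if (!is.null(config$paths$markers)) {
      ids <- readLines(config$paths$markers)
      markers <- marker_panel(ids[!startsWith(ids, "#") & nzchar(ids)])
    } else markers <- marker_panel()
  }

  if ("rank" %in% config$stages) {
    kept <- remove_mt_genes(expr, config$mt_pattern)
    report$counts$mt_removed <- nrow(expr) - nrow(kept)
    ranked <- percentile_rank(kept)
    write_table(data.frame(gene_id = rownames(ranked),
                           as.data.frame(unclass(ranked), check.names = FALSE)),
                file.path(config$out_dir, "ranks.tsv"), hdr)
    msum <- marker_rank_summary(ranked, markers, meta,
                                stratify_by = if (!is.null(meta)) "group" else NULL)
    write_table(msum, file.path(config$out_dir, "marker_summary.tsv"), hdr)
    report$marker_summary <- msum
  }

  if ("classify" %in% config$stages) {
    recs <- if (!is.null(config$paths$profiles)) {
      read_profiles(config$paths$profiles)
    } else {
      if (is.null(ranked)) stop("classify stage needs ranks or a profiles table",
                                call. = FALSE)
      # the in-memory dataset is one profile: marker rank by experimental group
      list(profile_record("dataset", unclass(ranked)[markers$gene_ids[1], ],
                          meta$group, sample_ids = colnames(ranked)))
    }
    cls <- classify_profiles(recs, config$classifier)
    write_table(cls$assignments, file.path(config$out_dir, "assignments.tsv"), hdr)
    write_table(cls$summary, file.path(config$out_dir, "priority_summary.tsv"), hdr)
    report$priority <- cls
    report$counts$profiles <- c(total = cls$n_total, retained = cls$n_retained)
  }

  if ("group" %in% config$stages) {
    tpm_like <- if (expr_unit(expr) == "counts") cpm(expr) else expr
    lv <- log2_expression(tpm_like, config$thresholds$marker)
    labels <- assign_groups(lv, config$thresholds)
    write_table(labels, file.path(config$out_dir, "labels.tsv"), hdr)
    report$counts$groups <- c(low = sum(labels$label == "low"),
                              high = sum(labels$label == "high"),
                              unassigned = sum(labels$label == "unassigned"))
    report$thresholds <- config$thresholds
  }

  if ("de" %in% config$stages) {
    if (is.null(labels)) stop("de stage requires the group stage", call. = FALSE)
    de_fit <- contamination_de(expr, meta, labels, config$de)
    write_table(de_fit$table, file.path(config$out_dir, "de_results.tsv"), hdr)
    report$de <- de_fit
    report$counts$de <- c(genes_in = de_fit$n_genes_in,
                          genes_tested = de_fit$n_genes_tested,
                          genes_filtered = de_fit$n_genes_in - de_fit$n_genes_tested,
                          up = sum(de_fit$table$call == "up"),
                          down = sum(de_fit$table$call == "down"))
  }

  if ("enrich" %in% config$stages) {
    if (is.null(de_fit)) stop("enrich stage requires the de stage", call. = FALSE)
    sets <- read_gmt(config$paths$gmt)
    enr <- hypergeometric_enrichment(de_genes(de_fit, "up"), sets,
                                     universe = de_fit$table$gene_id)
    write_table(enr, file.path(config$out_dir, "enrichment.tsv"), hdr)
    report$enrichment <- enr
    report$counts$enrich <- c(sets = nrow(enr),
                              significant = sum(enr$adjusted_p < 0.05, na.rm = TRUE))
  }

  if (!is.null(truth)) report$truth <- truth
  structure(report, class = "cp_report")
}

#' @export
print.cp_report <- function(x, ...) {
  cat("plexusQC run report (version ", x$version, ", seed ", x$seed, ")\n", sep = "")
  cat("stages:", paste(x$stages, collapse = " -> "), "\n")
  for (nm in names(x$counts)) {
    v <- x$counts[[nm]]
    cat(sprintf("  %-10s %s\n", nm,
                paste(names(v), v, sep = "=", collapse = ", ")))
  }
  if (!is.null(x$priority) && nrow(x$priority$summary)) {
    s <- x$priority$summary
    cat("priority fractions:",
        paste(sprintf("%d: %.1f%%", s$priority, 100 * s$fraction), collapse = ", "),
        "\n")
  }
  invisible(x)
}
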