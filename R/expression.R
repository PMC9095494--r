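#' Gene-by-sample expression matrix with a declared unit
#'
#' A `cp_expr` object is a numeric genes x samples matrix carrying a `unit`
#' attribute, one of `"counts"`, `"TPM"`, `"CPM"` or `"log2"`. All pipeline
#' stages take and return this container so that unit mistakes (e.g. feeding
#' already-normalized CPM into the CPM converter) are caught early.
#'
#' @param values numeric matrix with unique, non-empty rownames (gene ids) and
#'   colnames (sample ids). Values must be finite, and non-negative unless
#'   `unit = "log2"`.
#' @param unit expression unit, one of `"counts"`, `"TPM"`, `"CPM"`, `"log2"`.
#' @return a `cp_expr` object.
#' @export
expression_matrix <- function(values, unit = c("counts", "TPM", "CPM", "log2")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("`values` must have gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(gid))
    stop("duplicate gene ids: ", paste(unique(gid[duplicated(gid)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sid))
    stop("duplicate sample ids: ", paste(unique(sid[duplicated(sid)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression values must be finite", call. = FALSE)
  if (unit != "log2" && any(values < 0))
    stop("negative expression values are invalid for unit '", unit, "'", call. = FALSE)
  structure(values, unit = unit, class = c("cp_expr", "matrix", "array"))
}

#' @export
print.cp_expr <- function(x, ...) {
  cat(sprintf("cp_expr: %d genes x %d samples [%s]\n", nrow(x), ncol(x), expr_unit(x)))
  k <- min(5L, nrow(x)); m <- min(5L, ncol(x))
  print(unclass(x)[seq_len(k), seq_len(m), drop = FALSE])
  if (nrow(x) > k || ncol(x) > m) cat("...\n")
  invisible(x)
}

#' Expression unit of a matrix
#' @param x a `cp_expr` object.
#' @return the unit string.
#' @export
expr_unit <- function(x) {
  u <- attr(x, "unit")
  if (is.null(u)) stop("not a unit-annotated expression matrix", call. = FALSE)
  u
}

# subset while keeping class + unit
#' @export
`[.cp_expr` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out)) {
    attr(out, "unit") <- attr(x, "unit")
    class(out) <- c("cp_expr", "matrix", "array")
  }
  out
}

.delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, tsv = "\t", txt = "\t", csv = ",",
         stop("cannot infer delimiter from extension '.", ext,
              "' (use .tsv or .csv)", call. = FALSE))
}

#' Read a delimited expression matrix
#'
#' Expects a header row of sample ids and a first column of gene ids. The
#' delimiter is taken from the file extension (`.tsv`/`.txt` tab, `.csv`
#' comma), never sniffed from content. Lines starting with `#` are ignored.
#'
#' Duplicate gene ids are collapsed by summing when `unit = "counts"` (counts
#' are additive); for any other unit duplicates are an error, since TPM/CPM of
#' merged features is not the sum.
#'
#' @param path file path.
#' @param unit declared unit of the stored values.
#' @return a [expression_matrix()] object, row/column order as in the file.
#' @export
read_expression <- function(path, unit = c("counts", "TPM", "CPM", "log2")) {
  unit <- match.arg(unit)
  sep <- .delim_for(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          comment.char = "#", quote = "", stringsAsFactors = FALSE,
                          colClasses = NA)
  if (ncol(df) < 2) stop("expression table needs a gene-id column and >=1 sample", call. = FALSE)
  gid <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression values in ", path, call. = FALSE)
  rownames(vals) <- gid
  if (anyDuplicated(gid)) {
    if (unit != "counts")
      stop("duplicate gene ids cannot be collapsed for unit '", unit,
           "' (only counts are additive): ",
           paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
    ndup <- sum(duplicated(gid))
    vals <- rowsum(vals, group = gid, reorder = FALSE)
    message("collapsed ", ndup, " duplicate gene id row(s) by summing counts")
  }
  expression_matrix(vals, unit)
}

#' Write an expression matrix
#'
#' Values are serialized at full double precision (17 significant digits) so
#' that `read_expression(write_expression(x))` reproduces `x` exactly.
#'
#' @param m a `cp_expr` object.
#' @param path output path (`.tsv` or `.csv`).
#' @param header_lines optional character vector written as `#`-prefixed
#'   comment lines before the table.
#' @export
write_expression <- function(m, path, header_lines = NULL) {
  sep <- .delim_for(path)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines))
    writeLines(paste0("# ", header_lines), con)
  writeLines(paste(c("gene_id", colnames(m)), collapse = sep), con)
  body <- apply(unclass(m), 2, function(col) sprintf("%.17g", col))
  if (nrow(m) == 1L) body <- matrix(body, nrow = 1L)
  writeLines(paste(rownames(m), apply(body, 1, paste, collapse = sep), sep = sep), con)
  invisible(NULL)
}

#' Read a sample metadata table
#'
#' Required columns: `sample_id`, `group`. Optional: `sex` (female/male/unknown),
#' `age_bin` (ordered bins such as "70-74"); further columns are kept as-is.
#'
#' @param path TSV/CSV path.
#' @param expr optional `cp_expr`; if given, metadata sample ids must match its
#'   samples exactly (any order) and rows are reordered to match.
#' @return a data.frame with one row per sample.
#' @export
read_metadata <- function(path, expr = NULL) {
  sep <- .delim_for(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          comment.char = "#", quote = "", stringsAsFactors = FALSE)
  validate_metadata(df, expr)
}

#' Validate (and align) sample metadata
#' @param df data.frame with at least `sample_id` and `group` columns.
#' @inheritParams read_metadata
#' @return the validated data.frame, reordered to `expr`'s samples if given.
#' @export
validate_metadata <- function(df, expr = NULL) {
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata", call. = FALSE)
  if (any(is.na(df$group) | !nzchar(as.character(df$group))))
    stop("empty group labels in metadata", call. = FALSE)
  if ("sex" %in% names(df)) {
    bad <- setdiff(unique(df$sex), c("female", "male", "unknown"))
    if (length(bad)) stop("invalid sex value(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
  }
  if (!is.null(expr)) {
    if (!setequal(df$sample_id, colnames(expr)))
      stop("metadata sample ids do not match expression matrix samples", call. = FALSE)
    df <- df[match(colnames(expr), df$sample_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, fields tab-separated — set name,
#' description (discarded), then gene ids. Duplicate gene ids within a set are
#' deduplicated; duplicate set names are an error naming the line.
#'
#' @param path GMT file path.
#' @return a `cp_genesets` object: list with `sets` (named list of character
#'   vectors) and `universe` (NULL unless set later).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line ", i, " has fewer than 3 tab-separated fields", call. = FALSE)
    nm <- f[[1]]
    if (nm %in% names(sets))
      stop("duplicate gene-set name '", nm, "' at GMT line ", i, call. = FALSE)
    sets[[nm]] <- unique(f[-(1:2)])
  }
  gene_sets(sets)
}

#' Construct a gene-set collection
#' @param sets named list of character vectors (each non-empty, no duplicates).
#' @param universe optional character vector of background gene ids.
#' @return a `cp_genesets` object.
#' @export
gene_sets <- function(sets, universe = NULL) {
  if (length(sets) && is.null(names(sets)))
    stop("gene sets must be named", call. = FALSE)
  for (nm in names(sets)) {
    g <- sets[[nm]]
    if (!length(g)) stop("gene set '", nm, "' is empty", call. = FALSE)
    if (anyDuplicated(g)) stop("duplicate genes within set '", nm, "'", call. = FALSE)
  }
  structure(list(sets = sets, universe = universe), class = "cp_genesets")
}

#' @export
print.cp_genesets <- function(x, ...) {
  cat(sprintf("cp_genesets: %d set(s)%s\n", length(x$sets),
              if (is.null(x$universe)) "" else sprintf(", universe of %d genes",
                                                       length(x$universe))))
  invisible(x)
}

#' Write a rectangular result table
#'
#' Deterministic column order (as given), floats at 6 significant digits,
#' missing values serialized as `"NA"`. Used for every derived output table
#' (DE results, rank summaries, priority assignments, enrichment).
#'
#' @param rows a data.frame.
#' @param path output path (`.tsv` or `.csv`).
#' @param header_lines optional `#`-prefixed comment lines.
#' @export
write_table <- function(rows, path, header_lines = NULL) {
  if (!is.data.frame(rows)) stop("`rows` must be a data.frame", call. = FALSE)
  sep <- .delim_for(path)
  out <- rows
  for (j in seq_along(out)) {
    col <- out[[j]]
    if (is.double(col)) {
      s <- ifelse(is.na(col), "NA", sprintf("%.6g", col))
      out[[j]] <- s
    } else {
      out[[j]] <- ifelse(is.na(col), "NA", as.character(col))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  writeLines(paste(names(out), collapse = sep), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = sep)), con)
  invisible(NULL)
}

#' Read a table written by [write_table()]
#' @param path TSV/CSV path.
#' @return data.frame (strings "NA" parsed back to missing).
#' @export
read_table_file <- function(path) {
  sep <- .delim_for(path)
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    comment.char = "#", quote = "", stringsAsFactors = FALSE,
                    na.strings = "NA")
}

#' Choroid plexus marker panel
#'
#' @param gene_ids character vector of marker gene ids. The default panel is
#'   the canonical choroid plexus trio: transthyretin (TTR), folate receptor 1
#'   (FOLR1) and prolactin receptor (PRLR).
#' @param name panel name.
#' @return a `cp_markers` object.
#' @export
marker_panel <- function(gene_ids = c("TTR", "FOLR1", "PRLR"),
                         name = "choroid_plexus") {
  gene_ids <- as.character(gene_ids)
  if (!length(gene_ids)) stop("marker panel must contain >=1 gene", call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("duplicate marker gene ids", call. = FALSE)
  structure(list(name = name, gene_ids = gene_ids), class = "cp_markers")
}

#' @export
print.cp_markers <- function(x, ...) {
  cat(sprintf("marker panel '%s': %s\n", x$name, paste(x$gene_ids, collapse = ", ")))
  invisible(x)
}
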