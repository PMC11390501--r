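#' Read an InferCNV-style CNV matrix
#'
#' Parses the plain-text matrix layout written by InferCNV
#' (`infercnv.observations.txt` and relatives): first row cell names (quoted
#' or unquoted), first column gene names, whitespace- or tab-separated
#' values, genes kept in file order.
#'
#' @param path path to the matrix file.
#' @param kind `"discrete"` for 6-state HMM output (validated to `{1..6}`),
#'   `"continuous"` for denoised real-valued output.
#' @param dialect for `kind = "discrete"` only: `"state"` when the file
#'   already holds states 1..6; `"multiplier"` when it holds the copy-number
#'   multiplier encoding `{0, 0.5, 1, 1.5, 2, 3}`, which is mapped onto
#'   states 1..6. InferCNV emits both across versions.
#' @return a [discrete_cnv_matrix()] or [continuous_cnv_matrix()].
#' @export
read_cnv_matrix <- function(path, kind = c("discrete", "continuous"),
                            dialect = c("state", "multiplier")) {
  kind <- match.arg(kind)
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, comment.char = "",
                      quote = "\"'"),
    error = function(e) stop(sprintf("cannot parse matrix file '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  # header with one fewer field than the body puts genes into rownames;
  # otherwise the gene column arrives as the first (character) column
  if (ncol(raw) >= 1L && is.character(raw[[1L]])) {
    genes <- raw[[1L]]
    raw <- raw[, -1L, drop = FALSE]
  } else {
    genes <- rownames(raw)
  }
  if (ncol(raw) == 0L) stop(sprintf("no cell columns in '%s'", path))
  if (anyDuplicated(genes))
    stop(sprintf("duplicate gene id '%s' in '%s'",
                 genes[anyDuplicated(genes)], path))
  cells <- colnames(raw)
  non_num <- !vapply(raw, is.numeric, logical(1L))
  if (any(non_num))
    stop(sprintf("non-numeric values in column '%s' of '%s'",
                 cells[which(non_num)[1L]], path))
  vals <- as.matrix(raw)
  dimnames(vals) <- list(genes, cells)
  if (anyNA(vals)) {
    i <- arrayInd(which(is.na(vals))[1L], dim(vals))
    stop(sprintf("missing value at gene '%s', cell '%s' in '%s'",
                 genes[i[1L]], cells[i[2L]], path))
  }
  if (kind == "continuous") return(continuous_cnv_matrix(vals))
  if (dialect == "multiplier") vals <- multiplier_to_state(vals, genes, cells)
  if (any(vals != round(vals))) {
    i <- arrayInd(which(vals != round(vals))[1L], dim(vals))
    stop(sprintf(
      "non-integer discrete CNV value %s at gene '%s', cell '%s'",
      format(vals[i[1L], i[2L]]), genes[i[1L]], cells[i[2L]]))
  }
  discrete_cnv_matrix(vals)
}

# InferCNV multiplier encoding -> HMM state 1..6
multiplier_to_state <- function(vals, genes, cells) {
  codes <- c(0, 0.5, 1, 1.5, 2, 3)
  idx <- match(as.vector(vals), codes)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    i <- arrayInd(bad, dim(vals))
    stop(sprintf(
      "value %s at gene '%s', cell '%s' is not a CNV multiplier (%s)",
      format(vals[bad]), genes[i[1L]], cells[i[2L]],
      paste(codes, collapse = ", ")))
  }
  matrix(idx, nrow = nrow(vals), ncol = ncol(vals),
         dimnames = list(genes, cells))
}

#' Write a CNV matrix in InferCNV-style layout
#'
#' Cell names on the first row (unquoted), gene names in the first column,
#' tab-separated. Continuous values are written with enough digits to
#' round-trip within 1e-9.
#'
#' @param m a `DiscreteCnvMatrix` or `ContinuousCnvMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cnv_matrix <- function(m, path) {
  assert_cnv_matrix(m)
  if (ncol(m) == 0L || nrow(m) == 0L)
    stop("refusing to write a degenerate matrix (zero genes or cells)")
  body <- if (inherits(m, "DiscreteCnvMatrix")) {
    matrix(as.character(unclass(m)), nrow = nrow(m))
  } else {
    matrix(formatC(unclass(m), digits = 17, format = "g"), nrow = nrow(m))
  }
  lines <- c(paste(colnames(m), collapse = "\t"),
             paste(rownames(m),
                   apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop(sprintf("cannot write '%s': %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a gene ordering file
#'
#' Four tab-separated columns without header: gene id, chromosome, start,
#' end (1-based, inclusive, GFF-like), the convention of InferCNV's gene
#' ordering file. Rows are returned in genomic order: chromosomes in their
#' order of first appearance in the file, genes sorted by start position
#' within each chromosome.
#'
#' @param path path to the 4-column file.
#' @return a data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_positions <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE,
                      col.names = c("gene_id", "chrom", "start", "end"),
                      colClasses = c("character", "character",
                                     "character", "character")),
    error = function(e) stop(sprintf("cannot parse gene positions '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v) || any(v != round(v)))
      stop(sprintf("non-integer %s coordinate at line %d of '%s'",
                   col, which(is.na(v) | v != round(v))[1L], path))
    tab[[col]] <- as.integer(v)
  }
  if (anyDuplicated(tab$gene_id))
    stop(sprintf("duplicate gene id '%s' in '%s'",
                 tab$gene_id[anyDuplicated(tab$gene_id)], path))
  if (any(tab$start < 1L))
    stop("start coordinates must be >= 1 (1-based)")
  bad <- which(tab$end < tab$start)
  if (length(bad))
    stop(sprintf("end < start for gene '%s'", tab$gene_id[bad[1L]]))
  chrom_rank <- match(tab$chrom, unique(tab$chrom))
  tab <- tab[order(chrom_rank, tab$start), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
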