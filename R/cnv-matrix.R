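#' Discrete single-cell CNV matrix
#'
#' Wraps a genes x cells integer matrix of discrete copy-number states in the
#' six-level HMM encoding used by InferCNV: state 3 is copy-neutral, states
#' below 3 are losses, states above 3 are gains.
#'
#' @param states integer matrix, genes in rows, cells in columns; all values
#'   must lie in `{1, 2, 3, 4, 5, 6}` with no missing entries.
#' @param gene_ids,cell_ids character vectors naming rows and columns; taken
#'   from `dimnames(states)` when omitted.
#' @return an object of class `DiscreteCnvMatrix` (an integer matrix with
#'   dimnames and a class attribute).
#' @examples
#' m <- discrete_cnv_matrix(matrix(c(3L, 5L, 1L, 3L, 3L, 1L), nrow = 3,
#'                                 dimnames = list(paste0("g", 1:3),
#'                                                 paste0("c", 1:2))))
#' n_cells(m)
#' @export
discrete_cnv_matrix <- function(states, gene_ids = rownames(states),
                                cell_ids = colnames(states)) {
  if (!is.matrix(states)) stop("`states` must be a matrix")
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene and cell identifiers are required (dimnames or arguments)")
  if (length(gene_ids) != nrow(states) || length(cell_ids) != ncol(states))
    stop("id lengths do not match matrix dimensions")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (anyNA(states)) stop("missing values in discrete CNV matrix")
  sv <- as.vector(states)
  if (any(sv != as.integer(sv)))
    stop("non-integer discrete CNV state")
  bad <- which(sv < 1L | sv > 6L)
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(states))
    stop(sprintf(
      "discrete CNV state %s out of range {1..6} at gene '%s', cell '%s'",
      format(sv[bad[1L]]), gene_ids[i[1L]], cell_ids[i[2L]]))
  }
  storage.mode(states) <- "integer"
  dimnames(states) <- list(gene_ids, cell_ids)
  structure(states, class = c("DiscreteCnvMatrix", "CnvMatrix"))
}

#' Continuous single-cell CNV matrix
#'
#' Wraps a genes x cells numeric matrix of denoised CNV values on the
#' expression-ratio scale (copy-neutral around 1.0), as in InferCNV's
#' denoised observation output.
#'
#' @inheritParams discrete_cnv_matrix
#' @param values numeric matrix of finite values, genes in rows.
#' @return an object of class `ContinuousCnvMatrix`.
#' @export
continuous_cnv_matrix <- function(values, gene_ids = rownames(values),
                                  cell_ids = colnames(values)) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene and cell identifiers are required (dimnames or arguments)")
  if (length(gene_ids) != nrow(values) || length(cell_ids) != ncol(values))
    stop("id lengths do not match matrix dimensions")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (!all(is.finite(values))) stop("non-finite values in continuous CNV matrix")
  storage.mode(values) <- "double"
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(values, class = c("ContinuousCnvMatrix", "CnvMatrix"))
}

#' @export
print.CnvMatrix <- function(x, ...) {
  kind <- if (inherits(x, "DiscreteCnvMatrix")) "discrete" else "continuous"
  cat(sprintf("%s CNV matrix: %d genes x %d cells\n", kind, nrow(x), ncol(x)))
  invisible(x)
}

#' Number of cells / genes in a CNV matrix
#' @param m a `DiscreteCnvMatrix` or `ContinuousCnvMatrix`.
#' @return integer count.
#' @export
n_cells <- function(m) ncol(m)

#' @rdname n_cells
#' @export
n_genes <- function(m) nrow(m)

# strip the class so BLAS-heavy code sees a plain base matrix
cnv_values <- function(m) {
  v <- unclass(m)
  storage.mode(v) <- "double"
  v
}

assert_cnv_matrix <- function(m, arg = deparse(substitute(m))) {
  if (!inherits(m, "CnvMatrix"))
    stop(sprintf("`%s` must be a DiscreteCnvMatrix or ContinuousCnvMatrix", arg))
  invisible(m)
}
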