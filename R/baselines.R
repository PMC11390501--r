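#' PCA centroid-dispersion heterogeneity score
#'
#' The baseline of Ma and colleagues: project the cells into principal
#' component space (genes centered), keep the top `n_components` PCs, and
#' report the mean Euclidean distance of the cells from their centroid in
#' that space. Larger dispersion means more heterogeneous CNV profiles.
#'
#' Computed through the cell-by-cell Gram matrix of the centered profiles,
#' whose eigendecomposition gives the PC scores without forming the
#' gene-by-gene covariance.
#'
#' @param m a discrete or continuous CNV matrix with at least 2 cells.
#' @param n_components number of principal components retained; capped at
#'   `min(cells - 1, genes)`.
#' @return non-negative scalar dispersion score.
#' @export
ma_centroid_score <- function(m, n_components = 30L) {
  assert_cnv_matrix(m)
  if (ncol(m) < 2L) stop("need at least 2 cells")
  if (n_components < 1L) stop("`n_components` must be positive")
  x <- t(cnv_values(m))                       # cells x genes
  n <- nrow(x)
  g <- ncol(x)
  k <- min(n_components, n - 1L, g)
  xc <- x - rep(colMeans(x), each = n)
  if (k >= min(n - 1L, g)) {
    # full-rank projection: PCA is a rotation, distances are unchanged
    return(mean(sqrt(rowSums(xc^2))))
  }
  gram <- tcrossprod(xc)
  e <- eigen(gram, symmetric = TRUE)
  lambda <- pmax(e$values[seq_len(k)], 0)
  # squared PC-space distance of cell i from the (zero) centroid:
  # sum_j lambda_j * u_ij^2
  d2 <- as.vector(e$vectors[, seq_len(k), drop = FALSE]^2 %*% lambda)
  mean(sqrt(pmax(d2, 0)))
}

#' Median pairwise correlation-distance heterogeneity score
#'
#' The baseline of Guo and colleagues: for every unordered pair of cells,
#' compute `D = 1 - R` where `R` is the Pearson correlation of their CNV
#' profiles across genes, and report the median of the pairwise distances.
#' Scores lie in `[0, 2]`.
#'
#' Cells with a constant profile have undefined Pearson correlation; a pair
#' involving such a cell is assigned `D = 0` when the two profiles are
#' identical and `D = 1` otherwise (uncorrelated convention), with a
#' warning.
#'
#' @param m a discrete or continuous CNV matrix with >= 2 cells, >= 2 genes.
#' @return scalar in `[0, 2]`.
#' @export
guo_pairwise_score <- function(m) {
  assert_cnv_matrix(m)
  n <- ncol(m)
  if (n < 2L) stop("need at least 2 cells")
  if (nrow(m) < 2L) stop("need at least 2 genes")
  x <- cnv_values(m)                          # genes x cells
  g <- nrow(x)
  mu <- colMeans(x)
  xc <- x - rep(mu, each = g)
  ss <- colSums(xc^2)
  const <- ss <= .Machine$double.eps * g
  d <- matrix(NA_real_, n, n)
  if (any(!const)) {
    z <- xc[, !const, drop = FALSE] /
      rep(sqrt(ss[!const]), each = g)
    r <- crossprod(z)
    r[r > 1] <- 1
    r[r < -1] <- -1
    d[!const, !const] <- 1 - r
  }
  if (any(const)) {
    warning(sprintf(
      "%d constant-profile cell(s): pairs involving them use D = 0 (identical) / 1 (otherwise)",
      sum(const)))
    ci <- which(const)
    for (i in ci) {
      same <- colSums(abs(x - x[, i])) == 0
      d[i, ] <- ifelse(same, 0, 1)
      d[, i] <- d[i, ]
    }
  }
  stats::median(d[upper.tri(d)])
}
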