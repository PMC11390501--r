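#' Per-gene gain and loss alteration frequencies
#'
#' For each gene, the fraction of cells in which it is lost (discrete state
#' < 3) and gained (state > 3): the loss variant frequency (LVF) and gain
#' variant frequency (GVF) of the sample.
#'
#' @param m a [discrete_cnv_matrix()] with at least one cell.
#' @return an object of class `AlterationFrequencies`: list with `gene_ids`,
#'   `lvf`, `gvf` (vectors in `[0, 1]`) and `n_cells`.
#' @export
alteration_frequencies <- function(m) {
  if (!inherits(m, "DiscreteCnvMatrix"))
    stop("`m` must be a DiscreteCnvMatrix")
  n <- ncol(m)
  if (n < 1L) stop("matrix has zero cells")
  s <- unclass(m)
  structure(list(gene_ids = rownames(m),
                 lvf = rowSums(s < 3L) / n,
                 gvf = rowSums(s > 3L) / n,
                 n_cells = n),
            class = "AlterationFrequencies")
}

# frequency -> bin 1..10 over [0,0.1), [0.1,0.2), ..., [0.9,1.0];
# last bin closed. The epsilon absorbs float error in count/n at the
# decile boundaries without moving interior values.
frequency_bin <- function(f) {
  pmin(as.integer(floor(f * 10 + 1e-9)) + 1L, 10L)
}

#' Bin genes by alteration frequency
#'
#' Maps every gene once into one of 10 equal-width loss-frequency bins (by
#' LVF) and once into one of 10 gain-frequency bins (by GVF). Bins are
#' half-open `[0, 0.1), [0.1, 0.2), ...` with the last bin closed at 1.0.
#'
#' @param f an [alteration_frequencies()] result.
#' @param exclude_zero drop genes with frequency exactly 0 from that arm's
#'   histogram instead of counting them in the first bin.
#' @return named integer vector of length 20: 10 loss bins then 10 gain bins.
#' @export
bin_gene_counts <- function(f, exclude_zero = FALSE) {
  if (!inherits(f, "AlterationFrequencies"))
    stop("`f` must be an AlterationFrequencies object")
  lvf <- f$lvf
  gvf <- f$gvf
  if (exclude_zero) {
    lvf <- lvf[lvf > 0]
    gvf <- gvf[gvf > 0]
  }
  counts <- c(tabulate(frequency_bin(lvf), nbins = 10L),
              tabulate(frequency_bin(gvf), nbins = 10L))
  names(counts) <- c(paste0("loss_bin", 1:10), paste0("gain_bin", 1:10))
  counts
}

#' CNV complexity score (Shannon entropy of binned alteration frequencies)
#'
#' Quantifies subclonal complexity of a sample from its discrete single-cell
#' CNV matrix. Gain and loss frequencies of every gene are histogrammed into
#' 10 + 10 equal-width bins ([bin_gene_counts()]); the score is the Shannon
#' entropy, in bits, of the resulting distribution of gene counts:
#' `-sum(p_i * log2(p_i))` over bins with `p_i > 0`, where
#' `p_i = count_i / sum(counts)`.
#'
#' A sample with one dominant clone concentrates gene frequencies near 0
#' and 1 (few occupied bins, low entropy); a sample fragmented into many
#' subclones spreads frequencies across intermediate bins (high entropy).
#' The score is bounded by `log2(20) ~ 4.32` bits; an all-neutral sample
#' scores exactly 1 bit (all genes in the two zero bins) under the default
#' convention.
#'
#' @param m a [discrete_cnv_matrix()] with at least one gene and one cell.
#' @param exclude_zero see [bin_gene_counts()].
#' @return an object of class `ComplexityResult`: list with `frequencies`
#'   (the [alteration_frequencies()]), `bin_counts` (length 20),
#'   `bin_probs`, and `entropy` (bits).
#' @examples
#' m <- discrete_cnv_matrix(matrix(3L, 5, 4,
#'        dimnames = list(paste0("g", 1:5), paste0("c", 1:4))))
#' complexity_score(m)$entropy  # 1 bit: all mass in the two zero bins
#' @export
complexity_score <- function(m, exclude_zero = FALSE) {
  if (!inherits(m, "DiscreteCnvMatrix"))
    stop("`m` must be a DiscreteCnvMatrix")
  if (nrow(m) < 1L || ncol(m) < 1L)
    stop("degenerate matrix: need at least one gene and one cell")
  f <- alteration_frequencies(m)
  counts <- bin_gene_counts(f, exclude_zero = exclude_zero)
  total <- sum(counts)
  if (total == 0L)
    stop("no genes left after zero-frequency exclusion")
  probs <- counts / total
  structure(list(frequencies = f, bin_counts = counts, bin_probs = probs,
                 entropy = shannon_entropy(probs)),
            class = "ComplexityResult")
}

# entropy in bits with the 0 * log(0) == 0 convention
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' @export
print.ComplexityResult <- function(x, ...) {
  cat(sprintf("CNV complexity score: %.4f bits (%d genes, %d cells)\n",
              x$entropy, length(x$frequencies$gene_ids),
              x$frequencies$n_cells))
  invisible(x)
}

#' Split samples into high/low complexity groups at the median
#'
#' @param scores named numeric vector of per-sample complexity scores.
#' @return named character vector, `"H"` for scores above the median,
#'   `"L"` otherwise.
#' @export
complexity_groups <- function(scores) {
  if (length(scores) < 2L) stop("need at least two samples to split")
  med <- stats::median(scores)
  ifelse(scores > med, "H", "L")
}
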