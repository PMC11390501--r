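# Independent reference implementations used to check the package's fast
# paths. They deliberately share no code with R/: brute-force loops,
# stats::cor / prcomp, and hist()-style binning.

oracle_variance <- function(x) {
  mu <- sum(x) / length(x)
  acc <- 0
  for (v in x) acc <- acc + (v - mu)^2
  acc / length(x)
}

# naive histogram-and-sum entropy of a discrete matrix
oracle_entropy <- function(states, exclude_zero = FALSE) {
  n <- ncol(states)
  counts <- numeric(20)
  edges <- seq(0, 1, by = 0.1)
  bin_of <- function(f) {
    for (b in 1:10) {
      hi_ok <- if (b == 10) f <= edges[b + 1] + 1e-9 else f < edges[b + 1] - 1e-9
      if (f >= edges[b] - 1e-9 && hi_ok) return(b)
    }
    stop("frequency out of [0,1]")
  }
  for (g in seq_len(nrow(states))) {
    lvf <- sum(states[g, ] < 3) / n
    gvf <- sum(states[g, ] > 3) / n
    if (!exclude_zero || lvf > 0) counts[bin_of(lvf)] <- counts[bin_of(lvf)] + 1
    if (!exclude_zero || gvf > 0) counts[10 + bin_of(gvf)] <- counts[10 + bin_of(gvf)] + 1
  }
  p <- counts / sum(counts)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log2(pi)
  h
}

# exhaustive Mann-Whitney pair counting, ties half-credited
oracle_auc <- function(scores, labels) {
  pos <- scores[labels %in% c("poly", "polyclonal")]
  neg <- scores[labels %in% c("mono", "monoclonal")]
  acc <- 0
  for (p in pos) for (q in neg)
    acc <- acc + if (p > q) 1 else if (p == q) 0.5 else 0
  acc / (length(pos) * length(neg))
}

# full-SVD PCA centroid dispersion via prcomp + explicit distances
oracle_ma <- function(states, n_components = 30) {
  x <- t(states)
  k <- min(n_components, nrow(x) - 1, ncol(x))
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  sc <- pr$x[, seq_len(min(k, ncol(pr$x))), drop = FALSE]
  centroid <- colMeans(sc)
  mean(sqrt(rowSums(sweep(sc, 2, centroid)^2)))
}

# double-loop median pairwise correlation distance
oracle_guo <- function(states) {
  n <- ncol(states)
  d <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d <- c(d, 1 - stats::cor(states[, i], states[, j]))
  stats::median(d)
}

# closed-form equal-density point of two Gaussians with equal sd
oracle_gaussian_intersection <- function(mu1, mu2, sd1, sd2) {
  f <- function(x) stats::dnorm(x, mu1, sd1) - stats::dnorm(x, mu2, sd2)
  stats::uniroot(f, lower = min(mu1, mu2), upper = max(mu1, mu2))$root
}
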