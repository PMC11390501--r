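#' Per-cell CNV fluctuation score
#'
#' Measures how strongly a cell's copy-number profile fluctuates across the
#' genome: the population variance of its per-gene CNV values,
#' `sum((x - x_bar)^2) / n`. A copy-neutral cell has a flat profile and a
#' score near 0; aneuploid cells score high.
#'
#' By default the profile is centered on its own mean (`center = "mean"`).
#' `center = "neutral"` instead measures squared deviation from the
#' copy-neutral value, for workflows that prefer an absolute reference.
#'
#' @param profile numeric vector of CNV values over genes for one cell.
#' @param center `"mean"` (within-cell mean over genes) or `"neutral"`.
#' @param neutral the copy-neutral value used by `center = "neutral"`
#'   (1.0 on the expression-ratio scale, 3 for discrete states).
#' @return non-negative scalar; 0 iff the profile is constant (for
#'   `center = "mean"`).
#' @examples
#' cell_cnv_score(c(1, 1, 3, 3))  # variance of the profile: 1
#' @export
cell_cnv_score <- function(profile, center = c("mean", "neutral"),
                           neutral = 1.0) {
  center <- match.arg(center)
  if (length(profile) < 1L) stop("empty CNV profile")
  if (!all(is.finite(profile))) stop("non-finite values in CNV profile")
  mu <- if (center == "mean") mean(profile) else neutral
  mean((profile - mu)^2)
}

# column-wise (per cell) fluctuation scores for a genes x cells matrix
cell_cnv_scores <- function(values, center = "mean", neutral = 1.0) {
  if (nrow(values) < 1L || ncol(values) < 1L) stop("empty CNV matrix")
  mu <- if (center == "mean") colMeans(values) else rep(neutral, ncol(values))
  colMeans(sweep(values, 2L, mu, "-")^2)
}

#' Threshold between two score distributions
#'
#' Finds the crossing point of Gaussian kernel density estimates of the
#' observation and reference score distributions, searched on a 512-point
#' grid spanning the interval between the two sample means (Scott's
#' bandwidth on each sample). When the densities do not cross inside that
#' interval — e.g. the two distributions coincide — the midpoint of the two
#' means is returned and a warning is raised.
#'
#' @param obs_scores,ref_scores numeric vectors of per-cell scores.
#' @param n_grid number of grid points for the density evaluation.
#' @return scalar threshold lying between the two means.
#' @export
score_threshold <- function(obs_scores, ref_scores, n_grid = 512L) {
  if (length(obs_scores) < 1L || length(ref_scores) < 1L)
    stop("both score vectors must be non-empty")
  mu_o <- mean(obs_scores)
  mu_r <- mean(ref_scores)
  lo <- min(mu_o, mu_r)
  hi <- max(mu_o, mu_r)
  midpoint <- (mu_o + mu_r) / 2
  if (hi - lo <= .Machine$double.eps * max(1, abs(hi))) {
    warning("score distributions have equal means; using midpoint threshold")
    return(midpoint)
  }
  d_obs <- kde_on_grid(obs_scores, lo, hi, n_grid)
  d_ref <- kde_on_grid(ref_scores, lo, hi, n_grid)
  grid <- seq(lo, hi, length.out = n_grid)
  diff <- d_obs - d_ref
  s <- sign(diff)
  # strict sign changes only: a run of exact zeros (identical samples)
  # is not a crossing
  cross <- which(s[-1L] * s[-n_grid] < 0)
  if (length(cross) == 0L) {
    warning("densities do not cross between the means; using midpoint threshold")
    return(midpoint)
  }
  roots <- vapply(cross, function(i) {
    # linear interpolation of the density difference
    grid[i] + (grid[i + 1L] - grid[i]) * diff[i] / (diff[i] - diff[i + 1L])
  }, numeric(1L))
  roots[which.min(abs(roots - midpoint))]
}

kde_on_grid <- function(x, from, to, n) {
  bw <- if (length(x) >= 2L && stats::sd(x) > 0) stats::bw.nrd(x) else
    max(1e-8, abs(mean(x)) * 1e-8)
  stats::density(x, bw = bw, from = from, to = to, n = n)$y
}

#' Call malignant cells from observation vs reference CNV matrices
#'
#' Scores every cell in both matrices with [cell_cnv_score()] on their
#' shared genes, derives a threshold from the intersection of the two score
#' distributions ([score_threshold()]), and labels observation cells whose
#' score strictly exceeds the threshold as malignant. A score equal to the
#' threshold is non-malignant.
#'
#' @param obs,ref continuous (default) or discrete CNV matrices for the
#'   observation cells (e.g. hepatocytes) and the non-malignant reference.
#' @param center,neutral passed to the per-cell score; for discrete input use
#'   `neutral = 3`.
#' @return an object of class `MalignancyCall`: a list with `threshold`,
#'   `calls` (named character vector over observation cells, values
#'   `"malignant"`/`"non_malignant"`), `scores` (observation cells) and
#'   `ref_scores`.
#' @export
call_malignant <- function(obs, ref, center = c("mean", "neutral"),
                           neutral = 1.0) {
  assert_cnv_matrix(obs)
  assert_cnv_matrix(ref)
  center <- match.arg(center)
  shared <- intersect(rownames(obs), rownames(ref))
  if (length(shared) == 0L)
    stop("observation and reference matrices share no genes")
  if (length(shared) < nrow(obs) || length(shared) < nrow(ref))
    message(sprintf("scoring on %d shared genes (obs %d, ref %d)",
                    length(shared), nrow(obs), nrow(ref)))
  obs_scores <- cell_cnv_scores(cnv_values(obs)[shared, , drop = FALSE],
                                center, neutral)
  ref_scores <- cell_cnv_scores(cnv_values(ref)[shared, , drop = FALSE],
                                center, neutral)
  thr <- score_threshold(obs_scores, ref_scores)
  calls <- ifelse(obs_scores > thr, "malignant", "non_malignant")
  structure(list(threshold = thr, calls = calls,
                 scores = obs_scores, ref_scores = ref_scores),
            class = "MalignancyCall")
}

#' @export
print.MalignancyCall <- function(x, ...) {
  cat(sprintf("malignancy call: %d/%d observation cells malignant (threshold %.4g)\n",
              sum(x$calls == "malignant"), length(x$calls), x$threshold))
  invisible(x)
}
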