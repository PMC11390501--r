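as_poly_indicator <- function(labels) {
  if (is.logical(labels)) return(labels)
  lab <- as.character(labels)
  ok <- lab %in% c("mono", "monoclonal", "poly", "polyclonal")
  if (!all(ok))
    stop(sprintf("unknown label '%s' (expected mono/poly)", lab[!ok][1L]))
  lab %in% c("poly", "polyclonal")
}

#' Area under the ROC curve (Mann-Whitney pair statistic)
#'
#' The probability that a randomly chosen polyclonal sample scores strictly
#' above a randomly chosen monoclonal one, with ties credited 1/2 — the
#' rank-sum formulation, identical to the trapezoidal area under the ROC
#' curve with tie-grouped points (pROC's convention). Polyclonal is the
#' positive class.
#'
#' @param scores numeric vector of per-sample scores (higher = more likely
#'   polyclonal).
#' @param labels vector of `"mono"`/`"poly"` (or `monoclonal`/`polyclonal`,
#'   or logical with `TRUE` = polyclonal).
#' @return scalar AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  pos <- as_poly_indicator(labels)
  if (length(scores) != length(pos)) stop("scores and labels differ in length")
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve with Youden-point precision and recall
#'
#' Sweeps the sorted unique scores (plus infinite sentinels) as thresholds,
#' classifying a sample as polyclonal when `score >= threshold`. Reports the
#' full curve, the trapezoidal AUC, and precision/recall at the operating
#' threshold maximizing Youden's J (`tpr - fpr`), ties broken toward the
#' higher threshold.
#'
#' @inheritParams auc_score
#' @return an object of class `RocResult`: list with `thresholds`, `tpr`,
#'   `fpr`, `auc`, `precision`, `recall`, `operating_threshold`.
#' @export
roc_curve <- function(scores, labels) {
  pos <- as_poly_indicator(labels)
  if (length(scores) != length(pos)) stop("scores and labels differ in length")
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute a ROC curve")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tp <- vapply(thr, function(t) sum(scores >= t & pos), numeric(1L))
  fp <- vapply(thr, function(t) sum(scores >= t & !pos), numeric(1L))
  tpr <- tp / n_pos
  fpr <- fp / n_neg
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  j <- tpr - fpr
  best <- which(j == max(j))[1L]            # thresholds descend: first = highest
  op <- thr[best]
  pred <- scores >= op
  precision <- if (any(pred)) sum(pred & pos) / sum(pred) else NA_real_
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 precision = precision, recall = tpr[best],
                 operating_threshold = op),
            class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
  cat(sprintf("ROC: AUC %.4f, precision %.4f / recall %.4f at threshold %.4g\n",
              x$auc, x$precision, x$recall, x$operating_threshold))
  invisible(x)
}

method_registry <- function(n_components = 30L) {
  list(
    complexity = function(m) complexity_score(m)$entropy,
    ma = function(m) ma_centroid_score(m, n_components = n_components),
    guo = function(m) suppressWarnings(guo_pairwise_score(m)))
}

score_one_sample <- function(sample, methods, n_components = 30L) {
  reg <- method_registry(n_components)
  vapply(methods, function(mth) reg[[mth]](sample$matrix), numeric(1L))
}

#' Score every sample of a labelled cohort with the selected methods
#'
#' @param cohort list of `SimulatedSample` objects.
#' @param methods subset of `c("complexity", "ma", "guo")`.
#' @param n_components PCs retained by the `ma` baseline.
#' @return data.frame with `sample_id`, `label`, `n_cells` and one score
#'   column per method.
#' @export
score_cohort <- function(cohort, methods = c("complexity", "ma", "guo"),
                         n_components = 30L) {
  if (length(methods) == 0L) stop("empty method set")
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- lapply(cohort, function(s) {
    sc <- score_one_sample(s, methods, n_components)
    cbind(data.frame(sample_id = s$sample_id, label = s$truth$label,
                     n_cells = s$truth$n_cells, stringsAsFactors = FALSE),
          as.data.frame(as.list(sc)))
  })
  do.call(rbind, rows)
}

#' Benchmark heterogeneity methods on a labelled cohort
#'
#' Scores each sample with every requested method and evaluates how well
#' each score separates polyclonal from monoclonal samples: ROC curve, AUC
#' (pair statistic), precision/recall at the Youden point, and the Pearson
#' correlation of each score with the per-sample cell count (a robustness
#' diagnostic — methods contaminated by cell number correlate strongly).
#'
#' @param cohort list of `SimulatedSample` objects, or a pre-computed score
#'   table from [score_cohort()].
#' @param methods subset of `c("complexity", "ma", "guo")`.
#' @param n_components PCs for the `ma` baseline.
#' @return an object of class `BenchmarkResult`: list with `scores` (the
#'   per-sample table), `roc` (named list of [roc_curve()] results),
#'   `summary` (data.frame: method, auc, precision, recall,
#'   operating_threshold, r_with_n) and `ranking` (methods by decreasing
#'   AUC).
#' @export
benchmark_methods <- function(cohort, methods = c("complexity", "ma", "guo"),
                              n_components = 30L) {
  if (length(methods) == 0L) stop("empty method set")
  methods <- match.arg(methods, several.ok = TRUE)
  scores <- if (is.data.frame(cohort)) cohort else
    score_cohort(cohort, methods, n_components)
  missing_cols <- setdiff(methods, colnames(scores))
  if (length(missing_cols))
    stop(sprintf("score table lacks method column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  if (length(unique(as_poly_indicator(scores$label))) < 2L)
    stop("cohort must contain both monoclonal and polyclonal samples")
  roc <- lapply(methods, function(mth) roc_curve(scores[[mth]], scores$label))
  names(roc) <- methods
  summary <- data.frame(
    method = methods,
    auc = vapply(roc, `[[`, numeric(1L), "auc"),
    precision = vapply(roc, `[[`, numeric(1L), "precision"),
    recall = vapply(roc, `[[`, numeric(1L), "recall"),
    operating_threshold = vapply(roc, `[[`, numeric(1L),
                                 "operating_threshold"),
    r_with_n = vapply(methods, function(mth)
      stats::cor(scores[[mth]], scores$n_cells), numeric(1L)),
    stringsAsFactors = FALSE)
  structure(list(scores = scores, roc = roc, summary = summary,
                 ranking = summary$method[order(-summary$auc)]),
            class = "BenchmarkResult")
}

#' @export
print.BenchmarkResult <- function(x, ...) {
  cat("benchmark over", nrow(x$scores), "samples\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Simulate and score a cohort without holding it in memory
#'
#' Streams the cohort of [simulate_cohort()] one sample at a time (identical
#' per-sample seeds, hence bit-identical matrices) and keeps only the score
#' table — the form used for large benchmark cohorts.
#'
#' @inheritParams simulate_cohort
#' @inheritParams score_cohort
#' @param truth_only skip scoring and return only sample design columns
#'   (`n_cells`, `n_major_clones`).
#' @return data.frame like [score_cohort()]'s, plus `n_major_clones`.
#' @export
benchmark_cohort <- function(n_mono, n_poly, cfg = simulation_config(),
                             seed = 1L, methods = c("complexity", "ma", "guo"),
                             n_components = 30L, truth_only = FALSE) {
  plan <- cohort_plan(n_mono, n_poly, seed)
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    s <- simulate_sample(plan$kind[i], cfg, seed = plan$seed[i],
                         sample_id = plan$sample_id[i])
    row <- data.frame(sample_id = s$sample_id, label = s$truth$label,
                      n_cells = s$truth$n_cells,
                      n_major_clones = s$truth$n_major_clones,
                      stringsAsFactors = FALSE)
    if (!truth_only)
      row <- cbind(row, as.data.frame(as.list(
        score_one_sample(s, methods, n_components))))
    row
  })
  do.call(rbind, rows)
}
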