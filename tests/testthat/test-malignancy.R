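test_that("cell_cnv_score is the population variance of the profile", {
  expect_identical(cell_cnv_score(c(1, 1, 1, 1)), 0)
  expect_identical(cell_cnv_score(c(1, 1, 3, 3)), 1)   # mean 2, sum (x-2)^2/4
  set.seed(7)
  for (i in 1:5) {
    x <- stats::rnorm(50, mean = 1, sd = 0.4)
    expect_equal(cell_cnv_score(x), oracle_variance(x), tolerance = 1e-12)
  }
  expect_error(cell_cnv_score(numeric(0)), "empty")
})

test_that("cell_cnv_score is permutation-invariant and translation-covariant", {
  set.seed(11)
  for (i in 1:10) {
    x <- stats::rnorm(30)
    expect_equal(cell_cnv_score(sample(x)), cell_cnv_score(x))
    expect_equal(cell_cnv_score(x + stats::runif(1, -5, 5)),
                 cell_cnv_score(x), tolerance = 1e-12)
  }
})

test_that("adding genes farther from the cell mean never lowers the score", {
  set.seed(13)
  for (i in 1:10) {
    x <- stats::rnorm(40, 1, 0.1)
    mu <- mean(x)
    worst <- mu + max(abs(x - mu)) + stats::runif(1, 0.5, 3)
    expect_gte(cell_cnv_score(c(x, worst)), cell_cnv_score(x))
  }
})

test_that("neutral-centered option measures deviation from 1.0", {
  x <- c(1, 1, 1, 2)
  expect_equal(cell_cnv_score(x, center = "neutral"), 0.25)
  expect_equal(cell_cnv_score(rep(1, 5), center = "neutral"), 0)
})

test_that("score_threshold lands between separated clusters", {
  set.seed(5)
  obs <- stats::rnorm(200, 4, 0.1)
  ref <- stats::rnorm(200, 1, 0.1)
  thr <- score_threshold(obs, ref)
  expect_gt(thr, 1)
  expect_lt(thr, 4)
})

test_that("identical distributions fall back to the midpoint with a warning", {
  set.seed(9)
  x <- stats::rnorm(100, 2, 0.5)
  expect_warning(thr <- score_threshold(x, x), "midpoint")
  expect_equal(thr, mean(x), tolerance = 1e-8)
  expect_error(score_threshold(numeric(0), x), "non-empty")
})

test_that("KDE crossing matches the closed-form Gaussian intersection", {
  set.seed(7)
  a <- stats::rnorm(1000, 1, 0.2)
  b <- stats::rnorm(1000, 3, 0.2)
  truth <- oracle_gaussian_intersection(1, 3, 0.2, 0.2)  # = 2 by symmetry
  expect_equal(truth, 2, tolerance = 1e-6)
  expect_lt(abs(score_threshold(b, a) - truth), 0.15)
  expect_lt(abs(score_threshold(a, b) - truth), 0.15)
})

test_that("call_malignant recovers planted aberrant cells", {
  cfg <- small_cfg(noise_rate = 0)
  s <- simulate_sample("monoclonal", cfg, seed = 101, sample_id = "obs")
  obs <- emit_continuous(s, sigma = 0.1, seed = 102)
  neutral <- discrete_cnv_matrix(
    matrix(3L, nrow(obs), 150,
           dimnames = list(rownames(obs), sprintf("ref_%03d", 1:150))))
  ref <- emit_continuous(neutral, sigma = 0.1, seed = 103)
  call <- call_malignant(obs, ref)
  expect_named(call$calls)
  expect_length(call$calls, ncol(obs))
  # every observation cell carries at least the truncal events
  expect_gte(mean(call$calls == "malignant"), 0.95)
  # reference cells sit below the threshold
  expect_gte(mean(call$ref_scores <= call$threshold), 0.95)
})

test_that("degenerate and trivial malignancy cases behave per contract", {
  m <- rand_continuous(50, 30, seed = 21)
  expect_warning(call <- call_malignant(m, m), "midpoint")
  expect_true(all(call$calls %in% c("malignant", "non_malignant")))

  # constant-profile single observation cell scores 0, never malignant
  const_obs <- continuous_cnv_matrix(
    matrix(1, 50, 1, dimnames = list(rownames(m), "lonely")))
  call2 <- call_malignant(const_obs, m)
  expect_identical(unname(call2$scores), 0)
  expect_identical(unname(call2$calls), "non_malignant")

  # disjoint gene sets refuse to score
  other <- rand_continuous(10, 5, seed = 22)
  rownames_other <- paste0("zz", seq_len(10))
  dimnames(other) <- list(rownames_other, colnames(other))
  expect_error(call_malignant(other, m), "share no genes")
})
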