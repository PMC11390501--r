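test_that("configuration is validated", {
  expect_error(simulation_config(n_min = 0), "cell-count")
  expect_error(simulation_config(c_min = 1), "clone-count")
  expect_error(simulation_config(genome_size = 50, segment_genes = c(20, 200)),
               "genome smaller")
  expect_error(simulation_config(noise_rate = 1.5), "noise_rate")
  expect_error(simulation_config(p_dominant = 1), "p_dominant")
})

test_that("clone sizes sum exactly to N and every cell is assigned once", {
  for (seed in c(1, 2, 3)) {
    for (kind in c("monoclonal", "polyclonal")) {
      s <- simulate_sample(kind, small_cfg(), seed = seed)
      expect_identical(sum(s$truth$clone_sizes), s$truth$n_cells)
      expect_identical(ncol(s$matrix), s$truth$n_cells)
      expect_identical(length(s$truth$cell_assignment), s$truth$n_cells)
      expect_true(all(names(s$truth$cell_assignment) == colnames(s$matrix)))
      expect_true(all(s$truth$cell_assignment %in%
                        names(s$truth$clone_sizes)))
    }
  }
})

test_that("without noise every cell equals its clone's cumulative profile", {
  cfg <- small_cfg(noise_rate = 0)
  s <- simulate_sample("monoclonal", cfg, seed = 7)
  tr <- s$truth
  # rebuild each clone profile independently by replaying the event chain
  replay <- function(clone) {
    chain <- character()
    id <- clone
    while (!is.na(id)) {
      chain <- c(id, chain)
      id <- tr$clone_tree[[id]]
    }
    prof <- rep(3L, nrow(s$matrix))
    for (cl in chain)
      for (ev in tr$clone_events[[cl]])
        prof[ev[["start"]]:ev[["end"]]] <- ev[["state"]]
    prof
  }
  for (cell in sample(colnames(s$matrix), 10)) {
    expect_identical(unname(unclass(s$matrix)[, cell]),
                     replay(tr$cell_assignment[[cell]]))
  }
})

test_that("descendants inherit ancestral events except where overwritten", {
  cfg <- small_cfg(noise_rate = 0)
  s <- simulate_sample("polyclonal", cfg, seed = 19)
  tr <- s$truth
  sub <- names(tr$clone_sizes)[tr$clone_sizes > 0][1]
  cell <- names(tr$cell_assignment)[tr$cell_assignment == sub][1]
  prof <- unclass(s$matrix)[, cell]
  own <- rep(FALSE, nrow(s$matrix))
  for (ev in tr$clone_events[[sub]]) own[ev[["start"]]:ev[["end"]]] <- TRUE
  parent <- tr$clone_tree[[sub]]
  inter_own <- rep(FALSE, nrow(s$matrix))
  if (!is.na(parent) && parent != "root")
    for (ev in tr$clone_events[[parent]])
      inter_own[ev[["start"]]:ev[["end"]]] <- TRUE
  # outside the subclone's and intermediate's own events, the profile must
  # show the truncal state
  trunk <- rep(3L, nrow(s$matrix))
  for (ev in tr$clone_events[["root"]])
    trunk[ev[["start"]]:ev[["end"]]] <- ev[["state"]]
  keep <- !(own | inter_own)
  expect_identical(unname(prof[keep]), trunk[keep])
})

test_that("monoclonal dominance and polyclonal fragmentation hold", {
  s <- simulate_sample("monoclonal", seed = 23)
  frac <- max(s$truth$clone_sizes) / s$truth$n_cells
  expect_gte(frac, 0.80)
  expect_lte(frac, 0.97)

  set.seed(24)
  p <- simulate_sample("polyclonal", seed = 25)
  occupied_poly <- sum(p$truth$clone_sizes >= 1)
  occupied_mono <- sum(s$truth$clone_sizes >= 1)
  expect_gte(occupied_poly, 10 * occupied_mono)
})

test_that("same seed reproduces the sample bit-exactly", {
  a <- simulate_sample("polyclonal", small_cfg(), seed = 5)
  b <- simulate_sample("polyclonal", small_cfg(), seed = 5)
  expect_identical(unclass(a$matrix), unclass(b$matrix))
  expect_identical(a$truth$clone_sizes, b$truth$clone_sizes)

  co1 <- simulate_cohort(2, 2, small_cfg(), seed = 3)
  co2 <- simulate_cohort(2, 2, small_cfg(), seed = 3)
  expect_identical(lapply(co1, function(s) unclass(s$matrix)),
                   lapply(co2, function(s) unclass(s$matrix)))
  expect_identical(vapply(co1, function(s) s$truth$label, ""),
                   rep(c("monoclonal", "polyclonal"), each = 2))
  expect_identical(simulate_cohort(0, 0, seed = 1), list())
})

test_that("streamed benchmark scores reproduce the materialized cohort", {
  cfg <- small_cfg()
  streamed <- benchmark_cohort(2, 2, cfg, seed = 9, methods = "complexity")
  materialized <- score_cohort(simulate_cohort(2, 2, cfg, seed = 9),
                               methods = "complexity")
  expect_equal(streamed$complexity, materialized$complexity, tolerance = 1e-12)
  expect_identical(streamed$sample_id, materialized$sample_id)
})

test_that("emit_continuous maps states to multipliers and bounds the noise", {
  m <- disc(c(3, 5, 1, 6, 2, 4), 3, 2)
  s <- structure(list(matrix = m, truth = list(), sample_id = "x"),
                 class = "SimulatedSample")
  exact <- emit_continuous(s, sigma = 0)
  expect_identical(as.vector(unclass(exact)), c(1, 2, 0, 3, 0.5, 1.5))

  noisy <- emit_continuous(s, sigma = 0.1, seed = 77)
  expect_lt(max(abs(unclass(noisy) - unclass(exact))), 5 * 0.1)
  expect_error(emit_continuous(s, sigma = -1), "sigma")
})

test_that("noise jitters states by one level within [1, 6]", {
  cfg <- small_cfg(noise_rate = 0.5)
  s <- simulate_sample("monoclonal", cfg, seed = 33)
  clean <- simulate_sample("monoclonal", small_cfg(noise_rate = 0), seed = 33)
  d <- abs(unclass(s$matrix) - unclass(clean$matrix))
  expect_lte(max(d), 1)
  expect_gt(mean(d > 0), 0.2)   # at rate 0.5 many genes must move
  expect_true(all(unclass(s$matrix) >= 1 & unclass(s$matrix) <= 6))
})

test_that("polyclonal samples score higher complexity than monoclonal ones", {
  cfg <- small_cfg()
  co <- benchmark_cohort(8, 8, cfg, seed = 13, methods = "complexity")
  mono <- co$complexity[co$label == "monoclonal"]
  poly <- co$complexity[co$label == "polyclonal"]
  expect_gt(mean(poly), mean(mono))
})

test_that("simulated gene positions form a valid ordering table", {
  gp <- simulated_gene_positions(small_cfg())
  expect_identical(nrow(gp), 400L)
  expect_false(anyDuplicated(gp$gene_id) > 0)
  expect_true(all(gp$end >= gp$start))
  path <- withr::local_tempfile(fileext = ".txt")
  utils::write.table(gp, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  expect_identical(read_gene_positions(path)$gene_id, gp$gene_id)
})
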