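# programmatic fixtures; nothing is stored on disk

rand_discrete <- function(n_genes, n_cells, seed,
                          probs = c(.05, .1, .6, .1, .1, .05)) {
  set.seed(seed)
  m <- matrix(sample(1:6, n_genes * n_cells, replace = TRUE, prob = probs),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("c%03d", seq_len(n_cells))))
  discrete_cnv_matrix(m)
}

rand_continuous <- function(n_genes, n_cells, seed) {
  set.seed(seed)
  m <- matrix(1 + stats::rnorm(n_genes * n_cells, sd = 0.3),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("c%03d", seq_len(n_cells))))
  continuous_cnv_matrix(m)
}

disc <- function(values, n_genes, n_cells) {
  discrete_cnv_matrix(matrix(as.integer(values), n_genes, n_cells,
                             dimnames = list(sprintf("g%d", seq_len(n_genes)),
                                             sprintf("c%d", seq_len(n_cells)))))
}

small_cfg <- function(...) {
  simulation_config(n_min = 60L, n_max = 120L, genome_size = 400L,
                    segment_genes = c(10L, 40L), ...)
}
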