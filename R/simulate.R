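#' Simulation configuration for clonal single-cell CNV cohorts
#'
#' Collects the knobs of the clonal-structure generator. Defaults state the
#' cohort design used throughout: cell count `N ~ U[200, 2000]`, clone count
#' `C ~ U[5, 20]`, a dominant clone expected to hold 90% of the cells in
#' monoclonal samples, and a genome of 2000 genes over 22 chromosomes.
#' Copy-number events are contiguous runs of 20-200 genes at a non-neutral
#' state; clones inherit all ancestral events and add private ones.
#'
#' @param n_min,n_max inclusive bounds for the per-sample cell count N.
#' @param c_min,c_max inclusive bounds for the clone count C.
#' @param p_dominant binomial success probability for the dominant clone of
#'   a monoclonal sample.
#' @param genome_size number of genes.
#' @param n_chromosomes chromosomes the genes are spread over (metadata for
#'   gene ordering output; events are placed genome-wide).
#' @param truncal_events integer range (length-2) of truncal event counts.
#' @param private_events integer range of private event counts per clone.
#' @param subclone_events integer range of private event counts per
#'   polyclonal subclone.
#' @param segment_genes integer range of genes spanned by one event.
#' @param noise_rate per-gene probability that a cell's emitted state is
#'   jittered by +/-1 (clipped to `[1, 6]`). The default 0.02 emulates the
#'   residual segment-miscall noise of real InferCNV HMM output; 0 gives
#'   noiseless clone copies.
#' @param poly_flat if `TRUE`, polyclonal subclones attach directly to the
#'   root instead of to the C intermediate clones (flat topology).
#' @return a validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_min = 200L, n_max = 2000L,
                              c_min = 5L, c_max = 20L,
                              p_dominant = 0.9,
                              genome_size = 2000L,
                              n_chromosomes = 22L,
                              truncal_events = c(3L, 8L),
                              private_events = c(1L, 5L),
                              subclone_events = c(1L, 2L),
                              segment_genes = c(20L, 200L),
                              noise_rate = 0.02,
                              poly_flat = FALSE) {
  cfg <- list(n_min = as.integer(n_min), n_max = as.integer(n_max),
              c_min = as.integer(c_min), c_max = as.integer(c_max),
              p_dominant = p_dominant,
              genome_size = as.integer(genome_size),
              n_chromosomes = as.integer(n_chromosomes),
              truncal_events = as.integer(truncal_events),
              private_events = as.integer(private_events),
              subclone_events = as.integer(subclone_events),
              segment_genes = as.integer(segment_genes),
              noise_rate = noise_rate,
              poly_flat = isTRUE(poly_flat))
  if (cfg$n_min < 1L || cfg$n_max < cfg$n_min) stop("invalid cell-count range")
  if (cfg$c_min < 2L || cfg$c_max < cfg$c_min) stop("invalid clone-count range")
  if (cfg$p_dominant <= 0 || cfg$p_dominant >= 1)
    stop("`p_dominant` must lie in (0, 1)")
  for (fld in c("truncal_events", "private_events", "subclone_events",
                "segment_genes")) {
    r <- cfg[[fld]]
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] < 1L)
      stop(sprintf("`%s` must be a non-empty positive integer range", fld))
  }
  if (cfg$genome_size < cfg$segment_genes[2L])
    stop("genome smaller than the largest event segment")
  if (cfg$noise_rate < 0 || cfg$noise_rate > 1)
    stop("`noise_rate` must lie in [0, 1]")
  structure(cfg, class = "SimulationConfig")
}

runif_int <- function(n, lo, hi) {
  # U{lo..hi}; sample() alone mis-handles length-1 vectors
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# one CNV event: contiguous gene run at a non-neutral state
random_event <- function(cfg) {
  len <- runif_int(1L, cfg$segment_genes[1L], cfg$segment_genes[2L])
  start <- runif_int(1L, 1L, cfg$genome_size - len + 1L)
  state <- sample(c(1L, 2L, 4L, 5L, 6L), 1L)
  c(start = start, end = start + len - 1L, state = state)
}

random_events <- function(n_range, cfg) {
  n <- runif_int(1L, n_range[1L], n_range[2L])
  lapply(seq_len(n), function(i) random_event(cfg))
}

# apply events (ancestor-first) to a neutral baseline; later events win
events_to_profile <- function(event_chain, cfg) {
  prof <- rep(3L, cfg$genome_size)
  for (ev in event_chain)
    prof[ev[["start"]]:ev[["end"]]] <- ev[["state"]]
  prof
}

#' Simulate one labelled single-cell CNV sample
#'
#' Draws `N ~ U[n_min, n_max]` cells and `C ~ U[c_min, c_max]` clones, builds
#' a clone tree whose root carries the truncal events shared by all cells,
#' and emits each cell as its clone's cumulative profile (descendant events
#' overwrite ancestral ones on overlap) plus optional per-gene state jitter.
#'
#' Monoclonal samples place C leaf clones under the root with target sizes
#' `B(N, p_dominant)` for one dominant clone and `B(N, (1 - p_dominant)/(C - 1))`
#' for each rare clone. Polyclonal samples place C intermediate clones under
#' the root and attach `round(N/2)` small subclones (target size `B(N, 2/N)`)
#' uniformly at random to the intermediates; only subclones hold cells, so
#' each intermediate's events appear at frequency ~ 1/C. Raw binomial sizes
#' are renormalized to sum exactly to N by one multinomial draw with
#' probabilities proportional to `size + 1` (the smoothing keeps every clone
#' drawable), preserving the expected proportions.
#'
#' @param kind `"monoclonal"` or `"polyclonal"`.
#' @param cfg a [simulation_config()].
#' @param seed optional integer seed (set just before drawing).
#' @param sample_id identifier stored with the sample.
#' @return an object of class `SimulatedSample`: list with `matrix` (a
#'   [discrete_cnv_matrix()], genes x cells), `truth` (label, clone tree,
#'   per-clone events, clone sizes, cell assignment, `n_cells`,
#'   `n_major_clones`) and `sample_id`.
#' @export
simulate_sample <- function(kind = c("monoclonal", "polyclonal"),
                            cfg = simulation_config(), seed = NULL,
                            sample_id = NULL) {
  kind <- match.arg(kind)
  if (!inherits(cfg, "SimulationConfig"))
    stop("`cfg` must be a SimulationConfig")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sample_id)) sample_id <- paste0("sample_", kind)

  n_cells <- runif_int(1L, cfg$n_min, cfg$n_max)
  n_clones <- runif_int(1L, cfg$c_min, cfg$c_max)

  truncal <- random_events(cfg$truncal_events, cfg)
  clone_parent <- c(root = NA_character_)
  clone_events <- list(root = truncal)

  if (kind == "monoclonal") {
    ids <- paste0("clone", seq_len(n_clones))
    p_rare <- (1 - cfg$p_dominant) / (n_clones - 1L)
    raw <- integer(n_clones)
    for (i in seq_len(n_clones)) {
      clone_parent[ids[i]] <- "root"
      clone_events[[ids[i]]] <- random_events(cfg$private_events, cfg)
      raw[i] <- stats::rbinom(1L, n_cells,
                              if (i == 1L) cfg$p_dominant else p_rare)
    }
    bearing <- ids
  } else {
    inter <- paste0("clone", seq_len(n_clones))
    for (id in inter) {
      clone_parent[id] <- "root"
      clone_events[[id]] <- random_events(cfg$private_events, cfg)
    }
    n_sub <- as.integer(round(n_cells / 2))
    subs <- paste0("sub", seq_len(n_sub))
    attach_to <- if (cfg$poly_flat) rep("root", n_sub) else
      inter[runif_int(n_sub, 1L, n_clones)]
    raw <- integer(n_sub)
    for (i in seq_len(n_sub)) {
      clone_parent[subs[i]] <- attach_to[i]
      clone_events[[subs[i]]] <- random_events(cfg$subclone_events, cfg)
      raw[i] <- stats::rbinom(1L, n_cells, 2 / n_cells)
    }
    bearing <- subs
  }

  sizes <- as.vector(stats::rmultinom(1L, n_cells, prob = raw + 1))
  names(sizes) <- bearing

  # cumulative event chain root -> clone, then profile per cell-bearing clone
  chain <- function(id) {
    evs <- list()
    while (!is.na(id)) {
      evs <- c(clone_events[[id]], evs)
      id <- clone_parent[[id]]
    }
    evs
  }
  profiles <- vapply(bearing, function(id) events_to_profile(chain(id), cfg),
                     integer(cfg$genome_size))          # genes x clones

  assignment <- rep(bearing, sizes)
  states <- profiles[, match(assignment, bearing), drop = FALSE]

  if (cfg$noise_rate > 0) {
    hit <- which(stats::runif(length(states)) < cfg$noise_rate)
    if (length(hit)) {
      shift <- sample(c(-1L, 1L), length(hit), replace = TRUE)
      states[hit] <- pmin(pmax(states[hit] + shift, 1L), 6L)
    }
  }

  gene_ids <- sprintf("gene_%04d", seq_len(cfg$genome_size))
  cell_ids <- sprintf("%s_cell_%04d", sample_id, seq_len(n_cells))
  dimnames(states) <- list(gene_ids, cell_ids)
  names(assignment) <- cell_ids

  truth <- list(label = kind,
                clone_tree = clone_parent,
                clone_events = clone_events,
                clone_sizes = sizes,
                cell_assignment = assignment,
                n_cells = n_cells,
                n_major_clones = n_clones)
  structure(list(matrix = discrete_cnv_matrix(states), truth = truth,
                 sample_id = sample_id),
            class = "SimulatedSample")
}

#' @export
print.SimulatedSample <- function(x, ...) {
  cat(sprintf("%s sample '%s': %d cells, %d major clones, %d genes\n",
              x$truth$label, x$sample_id, x$truth$n_cells,
              x$truth$n_major_clones, nrow(x$matrix)))
  invisible(x)
}

# per-sample seeds derived once from the cohort seed, so that streaming
# consumers (benchmark_cohort) reproduce simulate_cohort exactly
cohort_plan <- function(n_mono, n_poly, seed) {
  if (n_mono < 0L || n_poly < 0L) stop("sample counts must be >= 0")
  total <- n_mono + n_poly
  if (total == 0L)
    return(data.frame(sample_id = character(), kind = character(),
                      seed = integer(), stringsAsFactors = FALSE))
  set.seed(seed)
  data.frame(
    sample_id = c(sprintf("mono_%03d", seq_len(n_mono)),
                  sprintf("poly_%03d", seq_len(n_poly))),
    kind = rep(c("monoclonal", "polyclonal"), c(n_mono, n_poly)),
    seed = sample.int(.Machine$integer.max, total),
    stringsAsFactors = FALSE)
}

#' Simulate a labelled cohort of monoclonal and polyclonal samples
#'
#' @param n_mono,n_poly numbers of monoclonal / polyclonal samples.
#' @param cfg a [simulation_config()] applied to every sample.
#' @param seed cohort seed; per-sample seeds are derived from it, so the
#'   cohort is bit-reproducible.
#' @return list of [simulate_sample()] results.
#' @export
simulate_cohort <- function(n_mono, n_poly, cfg = simulation_config(),
                            seed = 1L) {
  plan <- cohort_plan(n_mono, n_poly, seed)
  lapply(seq_len(nrow(plan)), function(i)
    simulate_sample(plan$kind[i], cfg, seed = plan$seed[i],
                    sample_id = plan$sample_id[i]))
}

#' Emit a continuous (denoised-style) matrix from a simulated sample
#'
#' Maps discrete states to the InferCNV multiplier scale
#' `{1 -> 0, 2 -> 0.5, 3 -> 1, 4 -> 1.5, 5 -> 2, 6 -> 3}` and adds
#' independent Gaussian noise `N(0, sigma^2)`.
#'
#' @param sample a `SimulatedSample` (or a `DiscreteCnvMatrix`).
#' @param sigma noise standard deviation, >= 0.
#' @param seed optional integer seed.
#' @return a [continuous_cnv_matrix()].
#' @export
emit_continuous <- function(sample, sigma = 0.1, seed = NULL) {
  m <- if (inherits(sample, "SimulatedSample")) sample$matrix else sample
  if (!inherits(m, "DiscreteCnvMatrix"))
    stop("`sample` must be a SimulatedSample or DiscreteCnvMatrix")
  if (sigma < 0) stop("`sigma` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  multipliers <- c(0, 0.5, 1, 1.5, 2, 3)
  vals <- matrix(multipliers[unclass(m)], nrow = nrow(m),
                 dimnames = dimnames(m))
  if (sigma > 0) vals <- vals + stats::rnorm(length(vals), 0, sigma)
  continuous_cnv_matrix(vals)
}

#' Gene positions for the simulated genome
#'
#' Genes are laid out consecutively (1 Mb apart, 100 kb long) across
#' `n_chromosomes` chromosomes in near-equal blocks, giving a gene ordering
#' table compatible with [read_gene_positions()].
#'
#' @param cfg a [simulation_config()].
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @export
simulated_gene_positions <- function(cfg = simulation_config()) {
  g <- cfg$genome_size
  per_chrom <- ceiling(g / cfg$n_chromosomes)
  chrom <- paste0("chr", ((seq_len(g) - 1L) %/% per_chrom) + 1L)
  idx <- stats::ave(seq_len(g), chrom, FUN = seq_along)
  start <- (idx - 1L) * 1000000L + 1L
  data.frame(gene_id = sprintf("gene_%04d", seq_len(g)),
             chrom = chrom, start = start, end = start + 99999L,
             stringsAsFactors = FALSE)
}
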