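# cnvcomplexity

Quantifies **intra-tumor subclonal complexity** from single-cell copy-number
variation (CNV) profiles, the kind inferred from scRNA-seq by InferCNV.

A tumor's clonal architecture leaves a readable imprint on per-gene
alteration frequencies across its malignant cells: a monoclonal tumor (one
dominant clone) concentrates gain/loss frequencies near 0 and 1, while a
polyclonal tumor (many small subclones) spreads them over intermediate
values. The package turns this into a per-sample score and ships everything
needed to validate it:

* **CNV complexity score** — for each gene, the loss and gain variant
  frequencies `LVF = n_loss / n`, `GVF = n_gain / n` (discrete state < 3 =
  loss, > 3 = gain) are histogrammed into 10 + 10 equal-width bins, and the
  score is the Shannon entropy of the bin occupancy,
  `H = -Σ p_i log2 p_i` (bits, bounded by `log2 20 ≈ 4.32`).
* **Malignant-cell calling** — a per-cell fluctuation score
  `CNVscore = Σ (X_i − X̄)² / n` (the variance of the cell's CNV profile),
  thresholded at the crossing of the kernel density estimates of the
  observation and reference score distributions.
* **Clonal-structure simulator** — labelled monoclonal/polyclonal cohorts
  with `N ~ U[200, 2000]` cells, `C ~ U[5, 20]` clones, binomial clone
  sizes (dominant `B(N, 0.9)`; polyclonal: `int(N/2)` subclones of size
  `B(N, 2/N)`), truncal + private contiguous CNV events on a clone tree.
* **Baselines and benchmarking** — the PCA centroid-dispersion score (mean
  distance of cells from their centroid in top-30 PC space) and the median
  pairwise correlation distance (`median of 1 − Pearson r` over cell
  pairs), plus ROC/AUC (Mann–Whitney pair statistic), precision/recall at
  the Youden point, and each score's correlation with cell number.

Intended for computational biologists post-processing single-cell CNV
calls who want a cell-number-robust heterogeneity statistic and a
simulation harness to test it.

## Worked example

```r
library(cnvcomplexity)

cfg  <- simulation_config(n_min = 300, n_max = 600)
mono <- simulate_sample("monoclonal", cfg, seed = 1, sample_id = "mono")
poly <- simulate_sample("polyclonal", cfg, seed = 2, sample_id = "poly")

complexity_score(mono$matrix)
#> CNV complexity score: 1.8749 bits (2000 genes, 466 cells)
complexity_score(poly$matrix)
#> CNV complexity score: 2.9172 bits (2000 genes, 497 cells)
```

The monoclonal sample scores ~1.9 bits (frequencies piled near 0 and 1, few
occupied bins); the polyclonal sample ~2.9 bits (its ~250 subclones push
frequencies into intermediate bins). Benchmarking a small labelled cohort:

```r
bench <- benchmark_methods(simulate_cohort(5, 5, cfg, seed = 42))
bench
#> benchmark over 10 samples
#>      method auc precision recall operating_threshold  r_with_n
#>  complexity   1         1      1           2.8672818 0.4353182
#>          ma   1         1      1          38.6687860 0.5104655
#>         guo   1         1      1           0.5596487 0.4403781
```

All three methods separate a 5+5 toy cohort perfectly (`auc = 1`); the
interesting column on large cohorts is `r_with_n`, the score's correlation
with cell number. Malignancy calling against an all-neutral reference:

```r
obs <- emit_continuous(mono, sigma = 0.1, seed = 3)
ref <- emit_continuous(discrete_cnv_matrix(matrix(3L, n_genes(obs), 200,
         dimnames = list(rownames(obs), sprintf("ref_%03d", 1:200)))),
       sigma = 0.1, seed = 4)
call_malignant(obs, ref)
#> malignancy call: 437/466 observation cells malignant (threshold 0.2664)
```

Here every observation cell carries at least the truncal events; the 29
cells left uncalled are those whose profile variance stays below the
density-crossing threshold.

## Command line

A single entry point with four subcommands (wrapper script in
`inst/scripts/cnvcomplexity`, or call `cnvcomplexity::cnv_cli()`):

```sh
cnvcomplexity simulate  --n-mono 100 --n-poly 100 --seed 1 --out cohort/
cnvcomplexity score     --cnv cohort/ --method all --out scores.tsv
cnvcomplexity malignancy --obs obs.tsv --ref ref.tsv --out calls.tsv
cnvcomplexity benchmark --cohort cohort/ --methods all --out report/
```

Global flags: `--seed`, `--force`, `--config cfg.json`, `--log-level`.
Every run writes a metadata JSON sidecar (version, seed, config hash);
identical argv + seed reproduce outputs byte-for-byte.

## Documentation

The methods vignette (`vignettes/cnv-complexity-methods.Rmd`) documents the
model, the simulator's event model and noise defaults, numerical
conventions (bin edges, tie handling, degenerate inputs) and known
limitations.
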