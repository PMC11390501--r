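---
title: "Quantifying subclonal complexity from single-cell CNV profiles"
author: "cnvcomplexity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying subclonal complexity from single-cell CNV profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvcomplexity)
```

## The problem

Tumors are mosaics of genetically related cell populations. Single-cell
RNA-seq lets us infer a per-gene, per-cell copy-number state (tools like
InferCNV emit a 6-level HMM call: state 3 copy-neutral, below 3 loss, above
3 gain), and the clonal structure of a tumor leaves a characteristic
imprint on those calls: a tumor dominated by a single clone shows gene
alteration frequencies concentrated near 0 and 1, while a tumor fragmented
into many small subclones spreads frequencies over intermediate values.
`cnvcomplexity` turns that imprint into a single per-sample statistic and
provides the machinery to validate it against simulated ground truth.

## The CNV complexity score

For a sample with $n$ malignant cells, each gene $g$ gets a loss variant
frequency and a gain variant frequency

$$\mathrm{LVF}_g = n_{\mathrm{loss},g} / n, \qquad
  \mathrm{GVF}_g = n_{\mathrm{gain},g} / n,$$

counting cells with discrete state $<3$ (respectively $>3$). Both
frequency sets are histogrammed into ten equal-width bins
$[0,0.1), [0.1,0.2), \dots, [0.9,1.0]$ — every gene contributes once to a
loss bin and once to a gain bin, 20 bins in total. With
$p_i = X_i / \sum_j X_j$ the fraction of gene-contributions in bin $i$, the
score is the Shannon entropy

$$H = -\sum_{i\,:\,p_i > 0} p_i \log_2 p_i \in [0, \log_2 20].$$

Design choices a user should know about:

* **Bin edges.** Half-open bins with a closed last bin guarantee each
  frequency maps to exactly one bin; a frequency of exactly 0.1 belongs to
  the second bin, 1.0 to the last. An epsilon of $10^{-9}$ absorbs floating
  point error of `count/n` at decile boundaries without moving any interior
  value.
* **Zero-frequency genes.** By default all genes are histogrammed, so the
  counts always sum to twice the gene number and an all-neutral sample puts
  every gene in the two zero bins, scoring exactly
  $H(\tfrac12,\tfrac12) = 1$ bit. The wording "mapping all the genes"
  motivates this default; because unaltered genes can dominate both zero
  bins, `exclude_zero = TRUE` offers the alternative convention that drops
  frequency-0 genes from each arm.
* **$0 \log 0 \equiv 0$** in the entropy sum.
* **H/L grouping.** `complexity_groups()` splits a cohort at the median
  score, the convention used when contrasting high- versus low-complexity
  tumors.

Because the score depends only on frequencies and bin occupancy — not on
how many cells produced them — it is largely insensitive to sample size,
which is the property the benchmark module quantifies.

## Malignant-cell calling

The per-cell fluctuation score is the population variance of the cell's
CNV profile, $\sum_i (X_i - \bar X)^2 / n$: copy-neutral cells have flat
profiles and score near zero, aneuploid cells score high. The published
formula's description of $\bar X$ ("the mean CNV value of gene $i$ in the
cell") does not define a scalar; we resolve it as the within-cell mean over
genes, which makes the score the profile variance and dimensionally
consistent with "degree of CNV fluctuation". Centering on the copy-neutral
value 1.0 instead is available via `center = "neutral"`.

The malignancy threshold is the crossing point of Gaussian kernel density
estimates (Scott's bandwidth, 512-point grid) of the observation and
reference score distributions, searched between the two sample means. When
several crossings exist the one nearest the midpoint of the means is used;
when none exists — identical distributions are the canonical case — the
midpoint of the means is returned with a warning. Cells must *exceed* the
threshold to be called malignant, so a score equal to the threshold (and in
particular a constant profile against a zero threshold) is non-malignant.

## Baseline heterogeneity metrics

Two published alternatives are implemented for comparison:

* **PCA centroid dispersion** (`ma_centroid_score`): cells are projected
  onto the top $k$ principal components (genes centered; default
  $k = 30$, matching the 30-PC convention of the upstream workflow; the
  value the original authors used for CNV input is not documented) and the
  score is the mean Euclidean distance of the cells from their centroid.
  Implemented through the eigendecomposition of the cell-level Gram
  matrix; when $k$ reaches the matrix rank the projection is a rotation
  and distances are computed directly, which is both faster and exact.
* **Median pairwise correlation distance** (`guo_pairwise_score`): the
  median over all unordered cell pairs of $D = 1 - R$ with $R$ the Pearson
  correlation of the two CNV profiles; $D \in [0, 2]$. Pearson correlation
  is undefined for a constant profile; such pairs are assigned $D = 0$ when
  the profiles are identical and $D = 1$ otherwise (with a warning), an
  "uncorrelated" convention the original description never needed because
  expression profiles are never constant.

## The simulated world

The simulator generates labelled cohorts for validating polyclonal-versus-
monoclonal discrimination. Its stated design: per-sample cell count
$N \sim U[200, 2000]$, clone count $C \sim U[5, 20]$ (integers), clone
sizes from binomial distributions — monoclonal: one dominant clone
$B(N, 0.9)$ and $C-1$ rare clones $B(N, 0.1/(C-1))$; polyclonal:
$\mathrm{int}(N/2)$ subclones of size $B(N, 2/N)$. The event model filling
in the unstated details is this package's own concrete instantiation:

* A genome of 2000 genes over 22 chromosomes. A CNV event is a contiguous
  run of 20–200 genes set to a non-neutral state (uniform over
  $\{1,2,4,5,6\}$).
* A clone tree rooted in a truncal ancestor carrying 3–8 events shared by
  every cell; each monoclonal clone adds 1–5 private events. Polyclonal
  samples use a two-level tree: $C$ intermediate clones (1–5 private
  events each) under the root, and the $\mathrm{int}(N/2)$ subclones (1–2
  private events) attached uniformly at random to intermediates. Only
  subclones hold cells, so intermediate events surface at frequency
  $\approx 1/C$ — intermediate bins of the histogram — which is what makes
  polyclonal entropy high. A flat topology (subclones directly under the
  root) is available via `poly_flat = TRUE`.
* Descendants inherit all ancestral events; on overlap the leaf-most event
  wins.
* Raw binomial sizes rarely sum to $N$; they are renormalized by a single
  multinomial draw with probabilities proportional to `size + 1`, which
  preserves the expected proportions (unlike trimming/padding) and keeps
  every clone drawable. Sizes sum to $N$ exactly, always.
* **Noise.** Each emitted gene state is jittered by $\pm 1$ (clipped to
  $[1,6]$) with probability `noise_rate = 0.02`. This default is a
  deliberate choice: real InferCNV discrete output always carries residual
  HMM miscalls, and a perfectly noiseless generator is degenerate for
  benchmarking — every within-clone cell pair is then bit-identical, so the
  median pairwise distance of every monoclonal sample collapses to exactly
  zero and that baseline separates the classes perfectly by an artifact no
  real data reproduces. Two percent per gene is a conservative stand-in
  for that residual miscall rate; it was fixed from this reasoning before
  any benchmark was run, not tuned to results.

What the generator does *not* emulate: chromosome-bounded events, read- or
expression-level noise, correlated (segment-level) miscalls, doublets, or
subclone phylogenies deeper than two levels. A green benchmark therefore
establishes that the score behaves as designed under planted clonal
structure with independent per-gene noise — not that it is optimal on any
real cohort.

`emit_continuous()` maps states to the multiplier scale
$\{0, 0.5, 1, 1.5, 2, 3\}$ and adds $N(0, \sigma^2)$ noise, producing the
denoised-style matrices the malignancy module consumes.

## Benchmarking

Polyclonal is the positive class. AUC is computed as the Mann–Whitney pair
statistic (ties half-credited), which the test suite verifies equals the
trapezoidal area under the tie-grouped ROC curve on every input. Precision
and recall are reported at the Youden-optimal threshold
($\max(\mathrm{tpr} - \mathrm{fpr})$, ties broken toward the higher
threshold) because no operating-point rule is prescribed upstream; the full
curve is returned so any other rule is recoverable. Each method's Pearson
correlation with per-sample cell count is reported as the robustness
diagnostic: the PCA baseline's top-$k$ truncation loses a growing share of
the dispersion as cell number (hence structure rank) grows, and per-cell
noise spreads over more principal directions in larger samples, so
cell-rich samples systematically score lower — the bias the entropy score
is designed to avoid.

## Reproducibility and numerics

Cohort generation derives one sub-seed per sample from the cohort seed, so
`simulate_cohort()` and the streaming `benchmark_cohort()` produce
bit-identical matrices, and identical CLI invocations produce byte-identical
outputs. Discrete matrices round-trip through the InferCNV-style text
format exactly; continuous matrices to 1e-9. Degenerate inputs (empty
profiles, single-class cohorts, zero-cell matrices, gene sets with no
overlap) raise errors rather than guessing.

## Known limitations

* The default simulated cohort is an easy discrimination task: the
  acceptance benchmark (`scripts/acceptance.R`) shows all three methods
  near or at AUC 1.0, so it validates correctness and robustness-to-N of
  the implementations rather than ranking the methods' power — separating
  the methods would need harder, noisier cohorts than this generator's
  stated design produces.
* The entropy score saturates for extreme cohorts (every bin occupied) and
  is insensitive to *which* bins are occupied; two samples with mirrored
  gain/loss structure can score identically.
* The KDE threshold assumes both score distributions are roughly unimodal;
  heavily multimodal reference populations may place the crossing between
  modes of the same distribution.
* Baselines are run on whatever matrix kind is supplied; comparing their
  absolute values across kinds (discrete vs continuous) is not meaningful.
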