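---
title: "Benchmarking differential abundance testing on synthetic single-cell data"
author: "scDAbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking differential abundance testing on synthetic single-cell data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scDAbench)
```

## The problem

Differential abundance (DA) testing asks which cells become more or less
frequent between experimental or clinical conditions in a multi-sample
single-cell dataset. Methods differ radically in their testing unit —
hyperspheres in marker space, kNN-graph neighbourhoods, random-walk
neighbourhood profiles, per-cell classifier scores, graph-smoothed
densities, or whole clusters — which makes a like-for-like comparison
non-trivial. scDAbench provides (i) a synthetic-data generator that plants
a known DA effect into datasets with linear-trajectory, branching-trajectory
or discrete-cluster topology, (ii) independent re-implementations of six DA
testing strategies on a shared kNN-graph substrate, and (iii) a
threshold-sweep evaluation that converts each method's heterogeneous scores
into AUROC/AUPRC against the planted per-cell ground truth.

## The generative model

`simulateTopology()` draws a latent structure and maps it through per-gene
response curves to negative-binomial counts
(variance $\mu + \phi\mu^2$, common dispersion $\phi = 0.5$):

* **linear** — latent time $u \sim U(0,1)$. Each gene carries a
  locally-activated program: its log-scale activity is a Gaussian bump in
  $u$ with random centre, width $\sim U(0.05, 0.15)$ and amplitude
  $\sim N(0, 4^2)$, on a baseline $\sim N(0.5, 1)$, passed through a
  softplus and scaled by a library factor of 3. Local activation is the
  property that matters: cells nearby in latent time share many active
  genes, so kNN neighbourhoods follow the trajectory. (An affine-in-$u$
  model produces a single structured principal component, and graph
  neighbourhoods then span a large fraction of the trajectory — no
  graph-based method can resolve a segment-sized DA region on such data.)
  Populations are five equal latent-time segments P1–P5.
* **branch** — a shared program as above plus branch-specific programs
  (centres in $[0.45, 1]$) activated past the branch point at $u = 0.4$;
  populations are two root segments and two segments per branch.
* **cluster** — per-population gene effects $\sim N(0,1)$; the default
  M1/M2/M3 split is deliberately unbalanced (M2 $\approx$ 52% of cells) to
  expose the majority-population failure mode; a balanced variant is
  produced with `subsamplePopulation()`.

The shipped study conditions are 7500 cells $\times$ 500 genes for the
trajectories, 2700 $\times$ 500 for the clusters, and six samples
(2 conditions $\times$ 3 replicates).

## Planting the DA effect

`plantDA()` assigns each cell a probability of originating from condition
C2,

$$P(C2)_i = \frac{w_i - \min w}{\max w - \min w}\,(p_{DA} - 0.5) + 0.5,$$

so the cell with the largest $w$ attains the DA ratio $p_{DA}$ exactly and
the smallest attains 0.5 (no effect). The logit-scale similarity $w$ is a
saturating ramp in the variance-weighted distance $d_i$ to the target
population's centroid in PC space:
$w_i = \mathrm{clamp}\{(d_0 - d_i)/\tau,\ \pm 4\}$ with $d_0$ the 90th
percentile of the target population's own centroid distances and
$\tau = d_0/20$. Two choices here are deliberate and were forced by
failure modes of more obvious alternatives:

* **Variance weighting (squared variance shares per PC).** With plain
  Euclidean distance in 50 PCs, the ~48 near-isotropic noise components
  dominate $d_i$ (chi concentration), and the planted field varies mainly
  along the high-dimensional noise radius — a direction graph diffusion
  cannot resolve. Weighting each PC by the square of its variance share
  confines the field to the structured components.
* **Saturation.** A smooth (e.g. Gaussian-logit) similarity leaves a
  gradient across the interior of the target population; the
  proportion-derived label threshold then cuts *inside* that plateau and
  labels become unresolvable in principle. The clipped ramp saturates well
  inside the population and reaches exactly 0.5 beyond $\simeq 1.2\,d_0$,
  so the label boundary coincides with the population edge.

`groundTruthLabels()` sets the threshold $t$ from the target population's
share $\rho$ of the dataset ($t = 1 - q$, $q$ the $(1-\rho)$-quantile of
$P(C2)$, clipped to $(0.05, 0.45)$) and labels cells PosLFC
($P(C2) > 1-t$), NegLFC ($P(C2) < t$) or NotDA. With an enrichment
planting ($p_{DA} > 0.5$) probabilities never fall below 0.5, so NegLFC
cannot occur; depletion plantings ($p_{DA} < 0.5$) are supported and mirror
the construction onto $[p_{DA}, 0.5]$. `assignConditions()` then draws each
cell's condition Bernoulli($P(C2)$), a replicate uniformly from R1–R3, and
forms the six samples.

## Batch effects

`addBatchEffects()` adds one Gaussian vector (i.i.d. entries, sd
`batchSd`) to the PC profile of every cell in a batch, exposing the full
0–1.5 grid. By default batches partition **whole samples** (re-drawn until
each batch holds both conditions). This choice is load-bearing: if cells
are assigned to batches uniformly at random within every sample, the batch
is unconfounded with the design — and because an i.i.d. 50-dimensional
shift separates the batch clouds almost immediately (cross-batch kNN edge
fraction $\approx$ 0 at sd 0.75 already), each cloud retains a complete,
balanced copy of the experiment and *no method degrades at all*.
Sample-level batches make the shift a genuine confounder: replicate pairs
straddle separated clouds, testing units see unequal sample composition,
and a sample-level batch covariate has something to absorb. Cell-level
assignment remains available (`by = "cell"`).

## The six DA methods

All clustering-free methods share the embedding and kNN graph from
`pcaEmbed()` (exact, centered, unscaled PCA; deterministic sign
convention) and `buildKnnGraph()` (union-symmetrized, binary kernel by
default; Gaussian and adaptive alpha-decay kernels available).

* **Hyperspheres (`runCydar`)** — random centres (10% of cells); cells
  within a radius form counting units; per-unit NB-GLM, spatial FDR with
  reciprocal-density weights; per-cell score = best $1 - \text{adjusted}$
  over containing spheres. The default radius is calibrated to a target
  median occupancy (100 cells) via the distance to the 100th neighbour —
  a fixed multiple of a typical kNN distance is unusable in 50
  dimensions, where occupancy explodes within a small factor of the
  median neighbour distance.
* **Multiscale logistic regression (`runDAseq`)** — per-cell features
  $(n_{C2} - n_{C1})/k$ over scales $k \in \{50, \dots, 500\}$;
  ridge-penalized logistic regression (penalty $10^{-3}$); DA measure
  $2\hat p - 1$; significance from the extreme null measures over 50 label
  permutations. The measure itself is permutation-free, so AUROC/AUPRC do
  not depend on the permutation count.
* **Graph KDE (`runMeld`)** — per replicate, each condition's indicator is
  smoothed by the low-pass filter $(I + \beta \tilde L)^{-1}$
  ($\tilde L$ the symmetric normalized Laplacian, $\beta = 60$, one sparse
  Cholesky factorization per graph, reusable across runs via
  `meldFilter()`); smoothed signals are normalized to unit mass (densities)
  and then per cell, giving a C2 likelihood that is averaged over
  replicates.
* **Random-walk NAM (`runCNA`)** — column-stochastic walk matrix with
  self-loops $\tilde A = (I + A)\,\mathrm{diag}(1 + \mathrm{colSums}
  A)^{-1}$, 3 steps; per-sample arrival masses row-normalize into the
  neighbourhood abundance matrix; the condition covariate is regressed on
  the top $k$ left singular vectors with $k$ chosen by the smallest
  multivariate F-test p-value; per-cell smoothed correlations
  $\gamma = V^{k^\star} D^{k^\star} \beta^{k^\star}$ are tested against a
  permutation null with a monotone tail-ratio FDR.
* **kNN neighbourhoods (`runMilo`)** — 10% index cells, first-order graph
  neighbourhoods, per-unit NB-GLM and spatial FDR (weights: reciprocal
  distance to the k-th neighbour); each cell receives the signed mean of
  $\mathrm{sign}(\log FC)(1 - \text{adjusted})$ over containing
  neighbourhoods. The mean, not the raw sum: overlapping neighbourhoods
  cover cells very unevenly, and the raw sum makes a cell's score track its
  membership count rather than the evidence. The shipped neighbourhood
  size is $k = 100$ (the graph for the other methods stays at $k = 30$):
  with ~30-cell units over six samples the per-unit NB test is underpowered.
* **Cluster-level (`runLouvain`)** — Louvain modularity clusters as units,
  NB-GLM per cluster, plain BH across clusters (clusters partition the
  cells, so no volume weighting), all member cells share the cluster score.

**NB-GLM details (`nbGlmTest`).** Per-unit negative binomial regression
with log link, ML dispersion (`MASS::theta.ml`) and likelihood-ratio
p-values; diverging dispersion estimates fall back to Poisson. Offsets
default to **median-of-ratios size factors** computed from the unit-count
matrix rather than raw per-sample cell totals: planting an enrichment
changes overall composition, so with raw totals every background unit is
genuinely depleted in relative abundance (log fold change $\approx -0.3$)
while labelled NotDA. Majority-invariant normalization — the same
assumption TMM makes inside edgeR-based tools — centres background units at
zero. Raw totals can still be supplied via `totals`.

**Spatial FDR (`spatialFDR`).** The weighted step-up rule: the rejection
threshold is the largest sorted $p_{(i)}$ with
$p_{(i)} \le \alpha \sum_{l\le i} w_{(l)} / \sum_l w_{(l)}$. With equal
weights this is exactly Benjamini–Hochberg (property-tested against a
brute-force oracle).

**Batch covariate.** Cydar/Milo/Louvain count cells per sample-by-batch
column and put condition + batch factors in the GLM design; units in which
one batch is empty drop the degenerate columns implicitly through the
per-unit fit. CNA residualizes the covariate and the NAM on the batch
factor. DA-seq and Meld have no batch pathway.

## Evaluation protocol

For each run, thresholds are placed at the 0–100th percentiles (1%
steps) of the method's own per-cell DA scores; predicted-positive means
score $\ge$ threshold; both PosLFC and NegLFC count as the positive class
(direction is ignored by default; `confusionAt()` offers a strict
direction-matching mode in which a detection with the wrong sign counts as
a false positive). ROC points are anchored at (0,0) and (1,1) and
integrated by trapezoid; the PR curve carries the highest-threshold
precision to recall 0. Cells a method did not assess score 0 — absence of
evidence must not count as discovery. Per (method, topology, DA ratio) the
median AUROC/AUPRC over target populations and seeds is taken, and the
mean of the three per-ratio medians is the headline "average"
(`aggregateMetrics()`).

## Numerical and design notes

* RNG: every randomized stage draws from a named child stream
  (`childSeed()`), so experiments vary one factor at a time and any single
  run is reproducible in isolation.
* kNN: exact brute-force search (BLAS-backed, chunked) with ties broken by
  cell index; no approximate search, for determinism.
* PCA: exact eigendecomposition of the gene-space covariance; loadings
  sign-fixed (largest-magnitude entry positive); rank-deficient requests
  truncate with a warning.
* Meld filter: $(I + \beta\tilde L)$ is an M-matrix, so smoothed signals
  are non-negative; solves use a cached sparse Cholesky factorization.
* Degenerate inputs: all-zero counting units report $p = 1$ and are
  flagged not assessed; empty samples in condition assignment trigger
  bounded resampling; `batchSd = 0` is the identity on embeddings.
* Benchmark sizes: the shipped grid (three topologies, three ratios, three
  targets, three seeds) was chosen as the smallest grid on which the
  per-ratio medians are stable to roughly $\pm 0.01$ for the strong
  methods; the full grid runs in well under an hour on one CPU.

## What passing the synthetic benchmark does and does not show

The generator emulates topology, planted enrichment, replicate structure
and batch confounding. It does not emulate library-size variation between
samples, doublets, ambient RNA, zero-inflation beyond the NB, CyTOF-style
measurement artifacts, or uncertainty in the ground truth itself (labels
are exact by construction). Method rankings on these data therefore speak
to each method's statistical machinery on a clean abundance signal, not to
robustness against the full messiness of real experiments; the original
data-analysis context also involves hyperparameter tuning that is held
fixed here (`benchConfig()` documents this package's defaults).

## Known limitations

* The NB-GLM uses plain per-unit ML dispersion; empirical-Bayes moderation
  (edgeR-style) would stabilize small-sample dispersion estimates.
* Milo's published neighbourhood refinement and the MNN kernel are not
  implemented.
* With six samples the CNA component grid is capped at $k \le 4$.
* Louvain's resolution is the dominant driver of its results, consistent
  with its reputation for hyperparameter sensitivity.
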