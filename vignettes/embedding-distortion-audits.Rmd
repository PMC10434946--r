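---
title: "Auditing distortion in low-dimensional single-cell embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing distortion in low-dimensional single-cell embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Single-cell expression analyses routinely reduce a cells × genes matrix from
thousands of dimensions to two, via PCA preprocessing followed by t-SNE or
UMAP, and then read biology off the resulting picture: which cells are
neighbors, which clusters are close, how mixed two batches are, how spread a
cell type is. Each of those readings presupposes that some geometric
property — local neighborhoods, global type relationships, or distances —
survived the reduction. This package quantifies how much of each property
actually survives, on data where the ground truth is known by construction.

The package has four working parts:

1. **Synthetic generators** (`generate_mixture_counts()` and friends) that
   produce scRNA-seq-like count matrices and geometric benchmarks with known
   structure.
2. **An embedding harness** (`pipeline_embed()`) that runs the standard
   reduction chains with pinned seeds and full provenance.
3. **Distortion metrics** (`jaccard_neighbor_distance()`,
   `type_ranking_correlation()`, `find_equidistant_groups()`,
   `mixing_fractions()`, `knn_label_predict()`, `inter_intra_ks()`,
   `relative_contrast()`, `jl_min_dimension()`, ...) — the mathematical
   core.
4. **Picasso** (`fit_picasso()`), a shape-constrained embedding that fits
   any dataset into an arbitrary 2D silhouette while preserving ambient
   distances comparably to UMAP — the constructive demonstration that the
   *shape* of a 2D embedding carries no evidence about the data.

## The synthetic world

`mixture_spec()` describes a discrete mixture of cell types. Counts for cell
$c$ and gene $g$ are drawn

$$ X_{cg} \sim \mathrm{NB}\!\left(\mu_{cg},\ \theta\right), \qquad
   \mu_{cg} = L_c \cdot p_{t(c),g}, \qquad
   L_c \sim \mathrm{LogNormal}(\log 5000,\ 0.3), $$

where $p_{t,\cdot}$ is type $t$'s expression proportion vector
(softmax of per-type log-means) and $\theta$ is a single shared
negative-binomial shape. Per-type log-means are a Gaussian gene baseline
(sd 1) plus small type wiggle (sd 0.1), with 10% of genes per type upshifted
by 1 log unit as markers.

Default scale is 5,000 cells × 2,000 genes with 20 equiproportional types.
These defaults were chosen once as a realistic desk-scale stand-in for a
droplet scRNA-seq experiment — median library size 5,000, overdispersion
$\theta = 2$, marker-driven discrete types — and are not tuned to any test
outcome. What the generator deliberately omits: UMI chemistry, ambient RNA,
doublets, gene–gene correlation beyond type structure, and continuous
trajectories (the Swiss roll covers the continuous case separately). A green
test therefore establishes that a metric behaves as claimed on clean,
discrete-type data; it does not certify behavior on, say, heavily batched or
continuous real tissue.

Geometric benchmarks: `generate_swiss_roll()` ($ (t\cos t, h, t\sin t) $
with exact arc-length ground truth), `generate_uniform_points()` (the
structureless null), `generate_equidistant_simplex()` (regular simplices —
the worst case for distance preservation in 2D), and `elephant_shape()`
(the closed curve drawn by four complex Fourier coefficients
$p_1 = 50-30i$, $p_2 = 18+8i$, $p_3 = 12-10i$, $p_4 = -14-60i$; the fifth
"wiggling trunk" parameter is omitted, and the orientation — trunk left,
feet down — is a fixed convention of this package).

## The metrics and their conventions

**Ambient space** means the log-normalized (target sum $10^4$, then
$\log(1+x)$), optionally HVG-restricted matrix. All metrics accept both L1
and L2; L2 is the default because it is what t-SNE/UMAP use.

- **Local**: `jaccard_neighbor_distance()` on k = 30 nearest neighbors
  (exact kNN, ties broken by cell index). 1.0 = disjoint neighbor sets.
- **Global**: types are ranked by mean pairwise inter-type distance
  (`type_distance_matrix()`; singleton types excluded with a warning), and
  rankings compared by Spearman correlation with average-rank ties — the
  coefficient is a package choice, recorded here because no specific rank
  statistic is canonical.
- **Distance**: `find_equidistant_groups()` finds groups of 3–8 cells whose
  pairwise distances sit within a relative band ε around a target (defaults:
  5th/95th percentile of a subsampled distance distribution for the
  near/far regimes). Groups are maximal cliques of the band graph found by
  Bron–Kerbosch with pivoting; cliques above size 8 are truncated to their 8
  lowest-index members, enumeration is capped by `limit`, and band-graph
  vertices by `node_cap` — all caps are determinism-preserving.
  `ratio_distortion()` then measures how the max/min distance ratio of each
  group inflates in the embedding.
- **Mixing / cluster validation**: `mixing_fractions()` (k = 30),
  `knn_label_predict()` (30% stratified holdout, k = 50 majority vote, vote
  ties broken by smaller mean neighbor distance), `inter_intra_ks()`
  (two-sample K-S statistic between pooled inter- and intra-type distances,
  pools subsampled to at most 10^6 with a recorded seed).
- **Norm choice**: `relative_contrast()` computes
  $(D_{\max}-D_{\min})/D_{\min}$ from random query points;
  `hvg_subset_contrast_protocol()` runs it over 5 random 1,000-gene subsets
  of the top 2,000 HVGs under both norms with the *same* query cells, so
  subset and norm are the only varying factors (the query scheme is not
  pinned by any external convention; fixed random queries are this
  package's choice).
- **Theory floor**: `jl_min_dimension(n, eps)` returns
  $8\ln(n)/\varepsilon^2$ — the linear-embedding dimension needed to keep
  all pairwise distances within ε. For 10,000 cells at 20% error: 1,842
  dimensions.

Replicates are never averaged away silently: `pipeline_embed()` runs each
stochastic chain n = 3 times (seeds s, s+1, s+2 in provenance) and the audit
tables carry one row per replicate.

## Picasso

The encoder is a multilayer perceptron (default widths 128, 64, ReLU, linear
2D head) trained with Adam on

$$ \mathcal{L} = w_s \cdot \mathrm{Chamfer}(E, S) \;+\;
   w_d \cdot \bigl(1 - \rho(d_{\text{ambient}}, d_{\text{embedded}})\bigr), $$

where the symmetric Chamfer distance is computed between the embedded
minibatch and the target shape (normalized to unit diameter), and $\rho$ is
the Pearson correlation of pairwise distances *within each minibatch*
(O(batch²), not O(n²)). Defaults $w_s = w_d = 1$. There is no decoder
reconstruction term — the distance term plays that role; whether the
original formulation also used a decoder is not settled in the public
record, so this package does not guess one into its defaults.

Numerical choices: network inputs are z-scored per column purely for
optimization conditioning (the ambient distances in the loss use the
untransformed input); the linear 2D head is initialized small so the cloud
grows from the origin into the silhouette rather than contracting from a
large random scatter; nearest-neighbor assignments in the Chamfer gradient
use an 1e-8 distance floor; the learning rate follows a cosine decay; and
minibatch order and initialization derive from the config seed, making fits
bit-reproducible. At equal loss weights the joint objective equilibrates at
a normalized shape-fit error of about 0.05 on the reference mixture — the
distance term actively holds a few extreme cells off the silhouette — so
shape-fit expectations tighter than that require raising `shape_weight`. `shape_fit_error()` reports
the Chamfer distance after centering and unit-diameter rescaling of both
clouds, so translation/scaling of a fit is not penalized — below ~0.05 the
cloud visibly fills the silhouette. Degenerate configs are rejected
(`shape_weight + distance_weight > 0`); a non-finite loss aborts with a
diagnostic rather than returning garbage.

The scientific point of `fit_picasso()` is the *comparison*: its inter- and
intra-type distance correlations to ambient, next to those of paired UMAP
runs (`inter_intra_correlation()`). When an elephant-shaped embedding
matches UMAP's fidelity numbers, apparent cluster layout in 2D is shown to
be an esthetic artifact.

## Design decisions taken where the ground was open

- **HVG statistic**: plain variance of log-normalized expression. The choice
  is recorded in provenance; any ranking statistic could be slotted in.
- **PCA determinism**: components' signs are fixed so each component's
  largest-magnitude loading is positive; truncated SVD is seeded.
- **Scaling before PCA** is exposed (`scale.`) but off by default; z-scoring
  genes is not universal practice and changes the ambient geometry.
- **Ranking-correlation aggregation across replicates**: correlations are
  computed per replicate embedding and then averaged (mean of correlations,
  not correlation of averaged rankings); flagged here because the
  alternative is defensible.
- **Equidistant-group semantics**: "a group" = a maximal in-band clique
  (truncated at size 8). An exhaustive subset-enumeration oracle in the test
  suite pins this definition.
- **t-SNE out-of-sample transform** is refused (`transform_new_points()` is
  UMAP-only): t-SNE has no native transform, and imitating one would blur
  the false-structure experiment the operation exists for.

## Tunable parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `k` (Jaccard / mixing) | 30 | neighborhood size at which local claims are made |
| `k` (label prediction) | 50 | vote size for cluster-validation accuracy |
| `target_sum` | 1e4 | per-cell total after normalization (counts) |
| PCA `d` | 50 | the standard preprocessing depth |
| UMAP `n_neighbors` / t-SNE perplexity | 15 / 30 | backend defaults; sweeps override |
| `epsilon` (equidistant band) | 0.05 | relative half-width of "equally distant" |
| Picasso epochs / batch / lr | 150 / 512 / 3e-3 (cosine decay) | pilot-run choice; the joint 1:1 loss equilibrates at Chamfer ~0.05 on the reference mixture |

## What the synthetic world does and does not show

Two findings from this package's own test suite illustrate the boundary
between implementation checks and data-dependent phenomena:

- **Mixing distortion** appears robustly: at an intermediate batch shift
  (ambient same-batch fraction ≈ 0.83), the 2D embedding reports the
  batches as fully unmixed (K-S ≈ 0.8 between ambient and embedded mixing
  distributions).
- **L1-versus-L2 relative contrast** is data-dependent. On iid uniform
  hypercubes — where the high-dimensional concentration theory applies —
  the package reproduces the textbook ordering (L1 contrast higher). On the
  reference NB mixture, however, the median log2(RC_L1/RC_L2) is slightly
  *negative*: the discrete marker structure rewards L2's squaring, and the
  minimal generator lacks the heavy-tailed noise and wide dynamic range of
  real scRNA-seq that favor L1 there. A green hypercube test therefore does
  not certify the ordering on any particular dataset; run
  `hvg_subset_contrast_protocol()` on the data at hand.

## Known limitations

- All large-matrix metrics materialize the n × n distance matrix; fine to
  ~10⁴ cells on a laptop, not beyond.
- L1 pairwise distances go through `stats::dist()` and are markedly slower
  than the BLAS-backed L2 path at large n.
- The audit treats cell labels as given truth; label noise is out of scope.
- Picasso here is this package's own implementation of the idea — encoder
  sizes, optimizer and schedule are package choices, with no claim of
  weight-for-weight equivalence to any other implementation.
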