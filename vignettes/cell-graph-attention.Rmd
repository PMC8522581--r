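---
title: "Classifying multi-type cell point patterns with graph attention"
author: "cellgat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying multi-type cell point patterns with graph attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellgat)
```

## The problem

Multiplexed immunofluorescence (mIF) histology reduces a tissue core to a
*multi-type spatial point pattern*: one planar coordinate per segmented
nucleus plus a phenotype label. With three phenotypes — pancytokeratin+
epithelial cells, CD3+CD8+ cytotoxic T lymphocytes (CTL) and FoxP3+
regulatory T cells (Treg) — the arrangement of tumour and immune cells
carries diagnostic signal for pancreatic disease: ductal adenocarcinoma
(PDAC), chronic pancreatitis (CP) and the precursor lesions IPMN, MCN and
PanIN can look deceptively similar under conventional review. `cellgat`
classifies such point patterns without any engineered morphology features:
positions and labels are the entire input.

## The model

Each sample becomes a **cell graph**. Every cell is joined to its $k$
nearest neighbours by Euclidean distance (default $k = 20$; ties broken by
the lower cell index, and the directed relation symmetrized by union so
the adjacency $A$ is binary and symmetric). With $\hat A = A + I$ and
$\hat D$ the degree matrix of $\hat A$, the propagation operator is the
symmetrically normalized adjacency

$$\tilde A = \hat D^{-1/2} \hat A \hat D^{-1/2}.$$

Cell-type symbols pass through a trainable embedding table into
$X_0 \in \mathbb{R}^{N \times d}$ (default $d = 30$), and $l$ graph
convolution layers (default $l = 2$) update the node features:

$$X_{t+1} = \sigma(\tilde A X_t W_t), \qquad t = 0, \dots, l - 1,$$

with $\sigma$ elementwise ReLU by default (tanh available). A
**self-attention read-out** pools the variable-size node matrix into a
fixed-dimension graph representation:

$$\alpha = \tanh(X_l)\,w, \qquad
  p_i = \frac{e^{\alpha_i}}{\sum_j e^{\alpha_j}}, \qquad
  s = X_l^{\top} p,$$

so $s \in \mathbb{R}^d$ is independent of the cell count $N$ and the
simplex weights $p$ rank every cell's contribution — the handle for model
interpretation. A single affine layer maps $s$ to two logits and a
soft-max yields the pairwise class probabilities. All parameters
(embedding, $W_t$, $w$, output head) are trained jointly by cross-entropy
with Adam (learning rate $10^{-3}$), one graph per step, 100 epochs, all
seeded. The forward pass, reverse-mode gradients and the optimizer are
implemented directly in R; graph operators are sparse matrices, so a
sample with a few thousand cells trains in milliseconds per step.

Because the probabilities depend on the coordinates only through the
graph, the whole pipeline is invariant to reordering cells and to rigid
motions of the sample; the unit of the coordinates is opaque.

## Multi-class consensus

Six-way classification of a heavily imbalanced cohort (the default
synthetic preset mirrors 56 CP / 41 PanIN / 21 MCN / 89 IPMN / 38
IPMN-associated PDAC / 143 PDAC = 388 samples) is delegated to the
$\binom{6}{2} = 15$ pairwise classifiers. The combination is rule-based,
not retrained:

1. **Unanimity stage.** Classes are tried in a priority order (default:
   PDAC, CP, IPMN, IPMN-associated PDAC, PanIN, MCN — strongest pairwise
   performers first). The first class whose five pairwise models all vote
   for it is returned.
2. **Tournament fallback.** Otherwise the class with most pairwise wins is
   returned, ties broken by the priority order.

The published description fixes this scheme only by example; the
unanimity-then-tournament rule with a configurable priority list is this
package's concretization, and the full 15-vote table is always returned
so any other rule can be audited downstream. Pairwise votes are arg-max
at 0.5 — with no calibration data, the raw soft-max is the only defensible
threshold.

## Morisita-Horn baseline

The single-number spatial baseline summarizes each image by one
Morisita-Horn dissimilarity. The bounding box is divided into a
$10 \times 10$ grid of half-open quadrats (max edges closed, so the
partition is exact); counts of epithelial vs pooled immune (CTL + Treg)
cells per quadrat give two vectors $x, y$, and

$$\mathrm{MH}(x, y) = \frac{2 \sum_i x_i y_i}
  {(\lambda_x + \lambda_y)\, X\, Y}, \qquad
  \lambda_x = \frac{\sum_i x_i^2}{X^2},\; X = \sum_i x_i,$$

is the canonical overlap form of the index (1 = proportionally identical,
0 = disjoint support); the feature is $1 - \mathrm{MH}$. The grid, the
phenotype pairing and the tree depth are all configuration, because no
single choice is canonical for three phenotypes: pooling immune cells
against epithelium matches the tumour-vs-immune contrast the index is
usually used for. A depth-3 CART tree (via `rpart`, impurity splits) on
this scalar is the comparison classifier; depth is capped because a
deeper tree on one feature only memorizes.

## Neighbourhood enrichment

Interpretation uses a permutation test on a sparser graph: each cell is
joined to its 3 nearest neighbours, and for every unordered phenotype
pair the observed number of joining edges is compared to its distribution
under label shuffles that keep the topology fixed (default 999
permutations). P-values carry an add-one pseudocount,
$p = (1 + \#\{\text{null} \ge \text{obs}\}) / (1 + n_{\mathrm{perm}})$,
so they are never zero and are uniform under the null to the resolution
the permutation count allows; calls use $\alpha = 0.05$ by default. The
same analysis can be restricted to the cells above an attention
percentile (90th for visual highlighting, 50th for enrichment input); the
graph is rebuilt on the subset, matching the idea of segmenting out the
attended region before asking which cell-pair adjacencies characterize
it. Edge counts are undirected and same-type pairs count each edge once,
so pair counts always sum to the total edge count.

## Synthetic study conditions

The real mIF cohort is restricted, so the package ships a generator that
is itself first-class, tested code. Each class is a Thomas-style cluster
process: per type, cluster parents fall uniformly in a window (default
$1000 \times 1000$ units), realized counts are Poisson around their
expectations, and offspring scatter isotropically (Gaussian, sd 35 units)
around a parent. The planted biology is the **mixing** coefficient: the
probability that an immune cell attaches to an *epithelial* parent rather
than one of its own type. Mixing 0 gives segregated immune infiltrates;
mixing 1 puts every immune cell at a tumour interface. The six-class
preset varies mixing (CP 0.50, IPMN 0.35, MCN 0.25, PanIN 0.30, PDAC
0.85, IPMN-associated PDAC 0.70) and immune abundance around a common
epithelial load of ~350 cells — roughly 500 cells per sample, at the
lower end of realistic mIF core sizes, chosen to keep cohort-scale
experiments cheap while exercising the same code paths as larger
samples. These values are the package's own choice of plausible
conditions; they are not fitted to any real cohort and make no claim of
biological fidelity beyond the qualitative structure (clustered
epithelium, interface-seeking immune cells, severe class imbalance).

What passing tests on these cohorts shows is therefore architectural: the
classifier can recover a planted difference in spatial mixing that a
single-number overlap index cannot, the read-out is permutation-sound,
and the enrichment null is calibrated. It does not show that real
pancreatic cohorts are separable to any particular accuracy — real data
differ in segmentation noise, phenotyping error, tissue-core geometry and
within-class heterogeneity that the generator does not emulate.

## Numerical and design choices

* Parameter initialization: small random normal (sd 0.1), seeded;
  initialization scale and the absence of weight decay are defaults the
  reference description leaves open.
* Soft-max (attention and output) subtracts the maximum before
  exponentiating; mathematically identical, overflow-safe.
* The output head is a single affine layer $d \to 2$ — the minimal
  reading of "a simple feed-forward network"; its depth is an obvious
  extension point.
* $k$ is clamped to $N - 1$ for tiny samples and a single-cell graph
  degenerates to $\tilde A = [1]$; duplicate coordinates are legal and
  ties resolve by cell index, so construction is deterministic.
* Disconnected graphs are allowed (k-NN at $k = 20$ keeps samples near
  connected without being complete); no connectivity repair is done.
* Attention percentiles use the linear-interpolation quantile with an
  inclusive threshold, so fully tied weights select every cell.
* The loss reweighting flag exists but is off by default: imbalance is
  handled by the pairwise/consensus structure, not by the loss.
* Stratified splits (80/20) and stratified 5-fold cross-validation report
  mean ± sample standard deviation across folds.

## Problem sizes in the shipped checks

The test suite and the acceptance script regenerate everything they
measure: the planted two-class benchmark uses 40 samples per class
(~400 cells each; 60 train / 20 test) with default hyperparameters and
100 epochs; the overlapping-mixing baseline cohort uses 100 samples per
class with 5-fold cross-validation; enrichment calibration uses 200
random-label samples of 100 cells at 199 permutations. These sizes were
chosen once as the smallest cohorts at which the three effects of
interest (separability of planted mixing, chance-level MH performance on
overlap, null uniformity) are stable across seeds.

## Limitations

The implementation is CPU-only and processes one graph per step; it is
sized for cohorts of hundreds of samples with up to a few thousand cells
each, not for whole-slide millions. The consensus rule is a documented
concretization, so published multi-class summaries should be treated as
qualitatively — not bitwise — reproducible. The Morisita-Horn baseline's
quadrat scheme and pairing are configurable precisely because no
canonical choice exists; conclusions about the baseline hold for the
configuration stated, and alternative generators (e.g. inhomogeneous
intensity, marker noise) are out of scope.
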