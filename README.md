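# cellgat

Cell-graph attention networks for classifying multi-type spatial point
patterns of cells into disease classes.

Multiplexed immunofluorescence (mIF) histology yields, per tissue core, a
planar point pattern: one coordinate per segmented nucleus plus a
phenotype label (here Epithelial, cytotoxic T lymphocyte CTL, regulatory
T cell Treg). The spatial interplay of tumour and immune cells is
diagnostic for pancreatic disease — ductal adenocarcinoma (PDAC), chronic
pancreatitis (CP) and the precursor lesions IPMN, MCN and PanIN — yet
hard to quantify with single-number indices. `cellgat` classifies these
patterns end-to-end from positions and labels alone, and explains its
predictions cell by cell. Intended users are computational pathology and
spatial-omics researchers working with cell-resolved point data.

## The model

Each sample becomes a k-nearest-neighbour cell graph (default k = 20,
union-symmetrized). With A the binary adjacency, Â = A + I and D̂ the
degree matrix of Â, the propagation operator is Ã = D̂^(−1/2) Â D̂^(−1/2).
Cell-type labels pass through a trainable embedding into X₀ ∈ ℝ^(N×d)
(d = 30) and l = 2 graph-convolution layers update the features:

    X_{t+1} = σ(Ã X_t W_t),  σ = ReLU.

A self-attention read-out pools the variable-size graph into a fixed
d-vector:

    α = tanh(X_l) w,   p = softmax(α),   s = X_lᵀ p,

where p ranks each cell's contribution and s feeds an affine soft-max
head producing pairwise class probabilities. Everything is trained
jointly by cross-entropy (Adam, lr 1e-3, 100 epochs, seeded; gradients
implemented in R). Around that core the package provides:

* a rule-based consensus combining the 15 pairwise classifiers into a
  six-class predictor (unanimity in priority order, then a round-robin
  tournament);
* a Morisita-Horn dissimilarity baseline (10×10 quadrats, epithelial vs
  pooled immune) with a depth-3 decision tree;
* cell-type neighbourhood enrichment/depletion by label-permutation tests
  on 3-NN graphs, optionally restricted to high-attention cells;
* stratified splits, 5-fold cross-validation, rank-based AUC, confusion
  matrices with support-weighted precision/recall/F1;
* a seeded Thomas-process-style generator of clustered multi-type
  patterns with a tunable tumour-immune interface-mixing coefficient,
  including a preset mirroring a 388-sample imbalanced six-class cohort.

## Worked example

Two synthetic classes differing only in how strongly immune cells seek
the epithelial interface (mixing 0.1 vs 0.9):

```r
library(cellgat)

cohort <- benchmark_cohort(n_per_class = 12, seed = 42, cells = 300)
cohort[[1]]
#> Point pattern 'A_001': 302 cells
#> Epithelial        CTL       Treg
#>        208         67         27
#> disease class: A

sp  <- split_cohort(cohort, train_fraction = 0.75, seed = 1)
fit <- cellgat(cohort[sp$train], classes = c("A", "B"),
               config = cellgat_config(seed = 7), epochs = 60)
fit
#> Cell-graph attention classifier: A (positive) vs B
#> d = 30, l = 2 layers, k = 20, activation = relu
#> trained on 18 graphs for 60 epochs; final loss 0.0007

pr <- predict(fit, cohort[sp$test], type = "prob")
truth <- vapply(cohort[sp$test], function(p) p$disease_class, character(1))
roc_auc(pr[, "A"], truth == "A")
#> [1] 1
```

The held-out AUC of 1 says the network fully recovers the planted
spatial-mixing difference. Interpretation runs through the attention
weights — here the top decile of cells (31 of 302) — and a permutation
enrichment test on the attended half of the sample:

```r
att <- predict(fit, cohort[[1]], type = "attention")[[1]]
length(attention_percentile_mask(att, 90))
#> [1] 31

er <- attention_subset_enrichment(cohort[[1]], att, q = 50,
                                  n_perm = 999, seed = 1)
er[, c("type_a", "type_b", "observed", "null_mean", "z", "call")]
#>       type_a     type_b observed  null_mean          z     call
#> 1 Epithelial Epithelial      156 101.917918  10.158350 enriched
#> 2 Epithelial        CTL       29 126.178178 -12.216681 depleted
#> 3 Epithelial       Treg       13  22.920921  -2.792688 depleted
#> 4        CTL        CTL       92  37.749750  12.246798 enriched
#> 5        CTL       Treg        6  14.109109  -2.539871 depleted
#> 6       Treg       Treg        8   1.124124   6.766225 enriched
```

Observed edge counts above the shuffled-label mean (positive z,
"enriched") mean the two phenotypes neighbour each other more than
expected given the topology; in this low-mixing class A sample the
attended region is dominated by same-type clustering and depleted
cross-type contact.

Cohort-scale runs (`cmd_simulate`, `cmd_train`, `cmd_predict`,
`cmd_explain`, `cmd_baseline`, `cmd_enrich`, or the `cellgat-cli`
wrapper) write CSV manifests, JSON checkpoints, cross-validation reports
and per-cell attention tables.

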