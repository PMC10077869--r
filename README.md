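# fcgnn — ensemble graph neural networks for functional-connectome classification

`fcgnn` classifies subjects into two groups from whole-brain functional
connectivity (FC). It is aimed at neuroimaging researchers who have
region-of-interest (ROI) BOLD time series or precomputed FC matrices — for
example resting-state fMRI parcellated with a 160-region whole-brain atlas
— and want a graph-based classification pipeline that runs end to end,
reproducibly, without a deep-learning framework dependency.

## The method

Per subject, pairwise Pearson correlations of the regional time series are
Fisher z-transformed, `z_ij = atanh(r_ij)`, giving a symmetric R × R
connectivity matrix with zero diagonal. Each matrix becomes a weighted
undirected graph G(N, E): nodes are the R regions, each node keeps edges to
its k strongest neighbours (|z|, union-symmetrised; default k = 10), edge
weights are |z|, and node i's feature vector is its full FC profile
`z_i·`.

Three graph neural networks classify the graphs, each built as three
message-passing layers → global mean pooling → softmax classifier:

| base | layer update | activation | dropout |
|---|---|---|---|
| GCN | `D̃^(-1/2) (A + I) D̃^(-1/2) X W` (weighted A) | ReLU | 0.3 |
| GAT | 8-head attention, `α_ij = softmax_j LeakyReLU(a_src·Wx_i + a_dst·Wx_j)` | eLU | 0.5 |
| GraphSAGE | `X W_self + mean_{j∈N(i)}(x_j) W_neigh`, K = 3, hidden 64 | ReLU | 0.3 |

All bases train with Adam (learning rate 0.01, weight decay 5e-4) on the
cross-entropy loss. A stacking ensemble then concatenates the three bases'
output logits (3 × 2 values) and trains a fully connected softmax meta head
on them, with the bases frozen.

Evaluation is stratified 10-fold cross-validation with class-balance
resampling (upsampling duplicates minority subjects, downsampling subsets
the majority; leak-free by default, with the leaky balance-before-split
protocol available and its cross-fold duplicate count reported), scoring
ACC = (TP+TN)/(TP+FP+FN+TN), SEN = TP/(TP+FN), SPE = TN/(TN+FP) and
trapezoidal ROC AUC per fold and averaged.

A seeded synthetic-cohort generator produces two-group cohorts of Fisher-z
FC matrices with a controllable group effect on a chosen edge subset, so
the full pipeline is testable without restricted clinical data. The layer
operators, backpropagation and Adam are implemented natively (R +
RcppArmadillo); no torch installation is required.

## Worked example

```r
library(fcgnn)

# a synthetic two-group cohort: 30 + 30 subjects, 30 regions,
# group difference of 1.5 z-units on 50 connected edges, noise sd 0.2
spec <- synthetic_cohort_spec(n_per_group = c(30, 30), n_regions = 30,
                              effect_size = 1.5, noise_sd = 0.2, seed = 1)
cohort <- generate_cohort(spec, graph_config(k = 10))

# stratified 10-fold cross-validation of the ensemble and its three bases
report <- run_cv(cohort,
                 optimizer = optimizer_config(epochs = 30, seed = 1),
                 n_folds = 10, fold_seed = 1,
                 policy = resampling_policy("upsample"))
report
```

```
<cv_report> 10 -fold cross-validation; sampling: upsample ( train_folds_only )
  cross-fold duplicate leakage: 0 subjects
    model sampling    ACC    SEN SPE AUC
 ensemble upsample 1.0000 1.0000   1   1
      gcn upsample 1.0000 1.0000   1   1
      gat upsample 0.9333 0.8667   1   1
     sage upsample 1.0000 1.0000   1   1
```

Each row is the mean over the ten held-out folds for one model: ACC is
held-out accuracy, SEN the true-positive rate on the patient group, SPE the
true-negative rate on the reference group, AUC the area under the ROC. With
a strong injected effect every model separates the groups essentially
perfectly (the attention model drops a few subjects at these small fold
sizes), and the leakage counter confirms no test subject entered a
training set. On a `null` cohort (`effect_size = 0`) the same pipeline
reports accuracies near 0.5 — chance — which is the behaviour that
validates the protocol. `report_tables(report, "out/")` writes the summary,
per-fold metrics and per-subject predictions as CSV plus a JSON echo of
every seed and configuration value.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/fcgnn.R simulate --out cohort/ --preset moderate --seed 1
Rscript inst/cli/fcgnn.R crossval --input cohort/ --out results/ --sampling both --epochs 50
```

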