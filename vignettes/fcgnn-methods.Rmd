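---
title: "Classifying functional connectomes with an ensemble of graph neural networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying functional connectomes with an ensemble of graph neural networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Resting-state fMRI yields, per subject, a matrix of BOLD time series for R
brain regions defined by an atlas (for the 160-region whole-brain atlas this
package defaults to, R = 160). Functional connectivity (FC) between two
regions is the Pearson correlation of their time series, variance-stabilised
by the Fisher z-transform `z = atanh(r)`. The scientific question is whether
a subject's whole-brain FC pattern carries enough signal to classify them
into one of two groups — patients versus controls, or two patient
subgroups.

`fcgnn` implements a graph-based answer: each subject's FC matrix is turned
into a weighted, undirected graph whose nodes are brain regions, and
graph neural networks classify the subject from that graph. Three base
architectures are trained independently and combined by a stacking
meta-learner.

## From time series to graphs

`compute_fc()` correlates all region pairs and applies `atanh` after
clipping `|r|` at `r_clip` (default 0.999999). Clipping keeps duplicated or
perfectly correlated series finite; the diagonal is forced to zero because
self-connectivity is uninformative and `atanh(1)` diverges.

`build_knn_graph()` sparsifies the dense FC matrix: each region keeps its
`k` strongest neighbours and the directed selections are merged by union
into an undirected edge set, so node degree is at least `k` but can exceed
it. Strength is `|z|` by default — a strongly anticorrelated pair is as
connected as a strongly correlated one — and edge weights default to `|z|`
so the adjacency stays nonnegative for degree-normalised propagation.
Signed values remain available (`weight_mode = "signed_z"`) and the full
signed FC profile of each node is always carried in the node-feature matrix
(row i is region i's FC row). Ties in the neighbour ranking are broken by
the lower node index so graph construction is deterministic across
platforms.

`k` is the one structural parameter with no canonical value; the default is
`k = 10`, and it is exposed in every entry point. Sensitivity is modest in
our synthetic experiments — the classification signal lives mostly in the
node features, with the KNN structure contributing a secondary, sparser
view — but denser graphs (larger `k`) cost proportionally more per
training step.

## The three base classifiers

All three models share the same scaffold: three message-passing layers, a
global mean pooling readout over the R node embeddings, and a fully
connected softmax classification layer. They differ in the layer operator:

* **GCN** — spectral-style propagation `act(D^{-1/2}(A + I)D^{-1/2} X W)`
  with self-loops added to the weighted adjacency. ReLU activation,
  dropout 0.3. The GCN is the only base that consumes the edge *weights*;
  its propagation requires a nonnegative adjacency.
* **GAT** — multi-head attention; per head, scores
  `e_ij = LeakyReLU(a_src·Wx_i + a_dst·Wx_j)` are softmax-normalised over
  each node's neighbourhood plus itself, and the update is the
  attention-weighted sum of transformed neighbours. Exponential-linear
  (eLU) activation, 8 heads, dropout 0.5. Hidden layers concatenate heads
  (8 heads × 8 features = 64); the final attention layer averages its heads
  into an 8-dimensional embedding, the standard output-layer convention.
  Self-attention is always enabled so isolated nodes are well defined.
* **GraphSAGE** — `act(X W_self + mean_neigh(X) W_neigh)` with K = 3
  layers of 64 hidden units, ReLU, dropout 0.3. The mean over an empty
  neighbourhood is the zero vector. GAT and GraphSAGE consume only the
  binary edge structure; their standard formulations are weight-free.

Depth and width not fixed by an architecture's published description
default to 3 layers × 64 hidden units for parity across bases. All models
train with Adam at learning rate 0.01 and weight decay 5e-4 on the
cross-entropy loss. Epochs (default 150) and mini-batch size (default 32)
are exposed; dropout is applied to each layer's input features and to the
pooled embedding, only during training, so evaluation is deterministic.

## The stacking ensemble

The three bases are trained independently on the same training subjects
(seeds derived from one optimizer seed), then frozen. Their output features
are concatenated and fed to a fully connected meta head with a softmax
output, trained with the same optimizer. Two open choices are surfaced as
configuration rather than guessed:

* *What are the "output features"?* Default: pre-softmax logits
  (`combine = "concat_logits"`, a 6-dimensional meta input for two
  classes); class probabilities are available as an option. The default
  follows from applying the softmax at the ensemble stage.
* *Is the meta head one layer or several?* Default: a single linear map
  3C → C (`meta_hidden = 0`); any hidden width can be requested.

Joint fine-tuning of bases and meta head (`freeze_bases = FALSE`)
back-propagates the meta loss through the base logits into every base. It
is implemented but non-default: independently trained, frozen bases are the
cleaner protocol and match the description of bases trained independently.

## Evaluation protocol

`run_cv()` performs stratified 10-fold cross-validation: per-fold class
proportions match the cohort's within one subject, fold assignment is
seed-deterministic, and per fold the three bases plus the ensemble are
trained on nine folds and scored on the held-out fold. Reported metrics are
accuracy, sensitivity, specificity (exact ratios from the confusion counts;
a metric with a zero denominator is reported as `NA`, never silently 0) and
trapezoidal ROC AUC using the positive-class softmax probability as the
score. Patients (label 1) are the positive class by default;
`positive_class` is carried by the cohort. Fold metrics are aggregated by
unweighted mean.

Class imbalance is handled by `resampling_policy()`: upsampling duplicates
randomly chosen minority subjects until the classes are equal (every
original subject is kept), downsampling keeps a random majority subset. The
*scope* matters scientifically: the default `train_folds_only` resamples
inside each training split and can never leak a test subject into training.
The alternative `before_split` balances the whole cohort before folds are
drawn, so duplicated subjects can straddle the train/test boundary;
`run_cv()` counts those cross-fold duplicates and reports the count
(`leakage_count`), which is zero by construction under the leak-free scope.
Both behaviours exist because balancing before splitting is a common —
and commonly undetected — protocol error that inflates accuracy; the
package makes the contrast measurable rather than pretending the choice
away.

## The synthetic cohort generator

Real consortium rs-fMRI cohorts are access-restricted, so the package ships
a generator that emulates the *container* of such data: per subject an
R × R symmetric Fisher-z matrix with zero diagonal, built as
`base_connectivity + group·effect_size·[edge in effect set] + site_offset +
N(0, noise_sd)` on the upper triangle, mirrored. Effects are injected
directly in z-space because the pipeline consumes z; that keeps recovery
analyses linear. Defaults chosen once: `base_connectivity = 0.2` z-units (a
typical resting-state mean), 50 effect edges drawn as a randomly grown
connected subgraph (a connected cluster of affected connections rather than
a degenerate single-node signal), no site effects unless requested.

Four presets fix the study conditions used in the package's own tests:
`separable` (effect 1.5, noise 0.2), `moderate` (0.4, 0.3), `null` (effect
0), and `imbalanced` (group sizes 110/55 at the moderate signal level,
mirroring a 2:1 first-episode vs recurrent subgroup imbalance). What the
generator does *not* emulate matters for interpretation: there is no
inter-subject covariance structure, no realistic spatial correlation
between edges, no scanner-specific noise spectra, and no heterogeneity of
effect across subjects. Passing the recovery tests therefore demonstrates
that the pipeline's machinery — graph construction, training, stacking,
cross-validation — extracts a known signal correctly; it does not
demonstrate clinical-grade accuracy on real cohorts.

## Numerical and engineering choices

* Attention scores are clamped at ±25 before exponentiation; within a
  neighbourhood the scores would need to differ by ~50 z-units for the
  clamp to distort the softmax materially. Gradients are zeroed in the
  clamped region.
* Mini-batches are composed once per training run (seeded) and their order
  is reshuffled each epoch; recomposing batches every epoch would change
  nothing statistically but costs graph re-batching every step.
* Dropout masks are generated from a per-step seed drawn from R's RNG, so
  full runs are bit-reproducible given the configured seeds, and
  `.Random.seed` is restored after every fit — fitting a model does not
  perturb the caller's RNG stream.
* Forward/backward passes run in compiled code (RcppArmadillo); a pure-R
  implementation of the same mathematics is kept in the package and the
  test suite asserts both agree to 1e-9 and match finite-difference
  gradients to 1e-4. Batches assume all graphs share one region count —
  true for any single-atlas cohort; mixed-size batches fall back to the R
  path.
* Hard classification ties (probability exactly 0.5) resolve to class 0.
  KNN ranking ties resolve to the lower node index. Both rules are
  deterministic across platforms.
* Degenerate inputs error early and by name: zero-variance time series
  (undefined correlation), non-symmetric FC matrices, `k ≥ R`,
  single-class training sets, subjects with mismatched region counts.

## Problem sizes in the shipped experiments

The test suite exercises signal recovery at 100 + 100 subjects with 60
regions and 50 training epochs — large enough that the separable preset is
recovered at ceiling and the null preset sits in the binomial chance band,
small enough to run on a laptop core in minutes. `scripts/acceptance.R`
re-runs the same protocol at 30 + 30 subjects with 30 regions and 30
epochs, reporting cross-validated ensemble accuracy and AUC for the three
balanced presets and the leakage contrast on the imbalanced one. Both sizes
are the package's own reporting choices; every function accepts
full-resolution inputs (R = 160 and cohort sizes in the thousands) with
cost growing roughly linearly in subjects and in edges per graph.

## Limitations

* The pipeline starts at ROI time series or FC matrices; fMRI
  preprocessing (motion correction, normalisation, nuisance regression) and
  atlas construction are out of scope.
* Only binary classification is implemented; the confusion-matrix metrics
  and the meta-head width assume two classes.
* No site-harmonisation step is provided; per-site offsets can be
  simulated, and site labels travel with cohorts, but correcting for them
  is left to the caller.
* Hyperparameters are fixed per run; there is no nested tuning loop, so
  reported cross-validation metrics evaluate the stated configuration, not
  an optimised one.
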