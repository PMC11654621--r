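---
title: "Generating synthetic multimodal bridges: models and methods"
author: "scbridge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating synthetic multimodal bridges: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Many single-cell experiments measure different molecular layers — transcriptome
(scRNA-seq), chromatin accessibility (scATAC-seq), histone marks — in
*different* cells. Such unpaired ("diagonal") designs share neither cells nor
features across modalities, so nothing links an RNA profile to an ATAC profile
directly. One route around this is *bridge integration*: if a paired
multimodal dataset exists, labels and features can hop from one unimodal
dataset to the other through it. `scbridge` manufactures that bridge when no
real one exists: a generative adversarial network learns the joint structure
of the modalities from their *embeddings* alone and emits synthetic cells that
carry a coordinate in every modality at once.

## The generative model

### Inputs

Each modality enters as a `ModalityView`: an `n_cells x C` embedding (PCA or
SVD scores; any dimensionality reduction works), a symmetric weighted kNN
graph over the same cells, and optionally the raw feature matrix and
cell/batch labels. Embeddings are used exactly as provided — the network is
trained directly on embedding coordinates, so rescaling would silently change
the geometry the critic sees; an optional per-column standardization flag
exists but is off by default. When views are combined into a `MultiomicStudy`,
every embedding is truncated to a common width `C`, never exceeding the
smallest matrix rank among the inputs (columns beyond the rank carry no
information and destabilize the pre-matching regression).

### Mini-batch pre-matching

Training happens on `(N, M, C)` tensors: N cells from each of M modalities,
stacked. In unpaired data the rows of different slices are different physical
cells, so which cells share a row matters enormously — random pairing teaches
the network only the global shape of each embedding, not the correspondence
between cell states.

Two devices impose that correspondence:

1. **Laplacian-eigenmap ordering.** For each modality we take the first
   nontrivial eigenvector of the symmetric normalized Laplacian
   `L = I - D^{-1/2} W D^{-1/2}` of the kNN affinity graph and sort cells by
   it. This eigenvector varies smoothly along the graph, so contiguous windows
   of the sorted order are structurally coherent neighbourhoods. The sign of
   an eigenvector is arbitrary; we canonicalize it (sum ≥ 0, first nonzero
   entry positive on an exact tie) so orderings are reproducible. The solver
   is a shift-free sparse symmetric eigensolver with a fixed deterministic
   start vector; for fewer than ~200 cells a dense eigendecomposition is used.
   A disconnected graph has no unique ordering and is an error by default;
   with `regularize = TRUE` a uniform affinity of 1e-8 is added between all
   pairs, which resolves the ambiguity while leaving within-component
   structure intact. Strongly separated cell populations routinely disconnect
   kNN graphs, so the training entry point enables this regularization
   automatically.

2. **Bayesian-ridge candidate scoring.** A source mini-batch is drawn from the
   reference modality (RNA by convention) as a random window of its sorted
   order. A Bayesian ridge regressor is fitted from the window's embedding
   coordinates to its eigenmap values (evidence maximization with conjugate
   Gamma hyperpriors of 1e-6, tolerance 1e-3, at most 300 iterations — the
   standard type-II maximum likelihood scheme). Fifty candidate windows are
   drawn from each other modality, and each is scored by the coefficient of
   determination of the regressor on the candidate's own (embedding, eigenmap)
   pair; the best-scoring candidate is coupled with the source. R² is the
   canonical goodness score of a fitted regressor, bounded above by 1, and a
   zero-variance candidate scores 0 by convention. Ties break to the first
   candidate drawn.

One subtlety the candidate scoring exposes: an eigenvector's sign is a gauge
freedom. The per-view canonical sign (sum ≥ 0) makes each modality
reproducible but says nothing about whether two modalities' eigenmaps run in
the same direction, and in practice the scoring couples windows with similar
eigenmap *value ranges*, so a flipped orientation would systematically pair
opposite ends of the two orderings. `prepare_study()` therefore aligns
orientations across modalities: a non-reference modality is negated when the
quantile profile of its negated eigenmap is closer (least squares over 101
quantiles — the discrete 1-d Wasserstein distance) to the reference
modality's profile than the unflipped one. The criterion uses only the shared
shape of the two distributions, is deterministic, and is immaterial for
symmetric profiles, where either orientation matches equally well.

Two further details were genuinely open and are decided here:

* *Candidate shape.* Candidates default to contiguous windows of the
  eigenmap-sorted order (`candidate_strategy = "window"`), the only reading
  under which sorting influences unpaired sampling; unordered random subsets
  remain available (`"random"`) for ablation.
* *Regressor lifetime.* The regressor is refitted for every source batch; at
  C ≤ 15 a fit costs a fraction of a millisecond, so caching would buy nothing.

For paired data the pre-match is skipped: cells are sorted lexicographically
by barcode and one shared random index set selects the same cells from every
modality.

### The WGAN-GP

The generator and critic are small 1-D convolutional networks whose
convolutions run **along the modality axis** (sequence length M, kernel size
2, stride 1): with M = 2 and kernel 2 this is the only axis layout consistent
with an `(N, M, C)` tensor, and it is exactly the mechanism that lets the
network couple modalities. Channels are the embedding dimensions. Same-length
(right zero) padding keeps the sequence length at M through every layer —
valid padding would collapse M = 2 to a single position after one layer.

* **Generator**: a per-cell Gaussian noise vector (`latent_dim`, default 64)
  is lifted by a rectified affine layer to an M-position sequence, then three
  Conv1D layers with filter counts (512, 128, C) by default; batch
  normalization (momentum 0.99, epsilon 1e-3) after the first and second
  convolutions, ReLU activations. The output convolution is linear: embedding
  coordinates are signed, and a rectified output could never produce negative
  PCA scores. The noise-input design is a standard GAN choice recorded in each
  run's provenance.
* **Critic**: two Conv1D layers (128, 512 filters), ReLU, and a single affine
  unit producing one unbounded score per sample. The critic contains **no**
  batch normalization — the gradient penalty is defined per sample and batch
  statistics would couple samples, invalidating it. This is asserted
  structurally in the tests.

Losses are the Wasserstein pair: the critic minimizes
`mean(fake) - mean(real) + lambda * GP`, the generator minimizes
`-mean(fake)`. The gradient penalty draws one `e ~ Uniform(0,1)` per sample,
interpolates `xhat = e*real + (1-e)*fake`, and penalizes
`(||grad_xhat critic(xhat)||_2 - 1)^2`, the norm over the full M x C sample.
`lambda = 10` and 5 critic updates per generator update are the standard
WGAN-GP settings (both exposed in `train_config()`). The generator uses Adam
(learning rate 0.001, beta1 0.5, beta2 0.9, epsilon 1e-07); the critic uses
RMSprop (learning rate 0.0005).

No deep-learning framework is involved: layers, batch-norm and both backward
passes are explicit dense linear algebra. Because every activation is ReLU,
the network is piecewise linear, and at fixed activation masks the critic's
input gradient is an exact product of masked convolution operators; the
parameter gradient of the gradient penalty (a double backward) therefore has a
closed form, which is what the implementation uses. Both backward passes are
verified against central finite differences in the test suite at tolerance
1e-5.

Each critic update consumes a freshly assembled mini-batch tensor. A
non-finite loss — a real failure mode of adversarial training at some
filter/width combinations, which the grid-search helper `sweep_grid()` maps —
is handled per `nan_policy`: `"abort"` (default) raises immediately,
`"restart"` re-seeds and retries up to 3 times. Completed loss histories are
finite by construction.

Adversarial training does not converge to a point — at equilibrium the
generator orbits the data distribution, and snapshots a few hundred steps
apart differ noticeably. Generation therefore uses an exponential moving
average of the generator weights (decay 0.995 per generator step, zero-
initialized with Adam-style bias correction; `ema_decay = 0` disables it),
the standard stabilizer for this oscillation. Generation runs in inference
mode (batch norm uses running statistics), so output depends only on
parameters and the noise seed. The default number of synthetic cells equals
the reference modality's size.

### Semisupervised training

With batch labels present, one model is trained per batch on that batch's
cells only and the outputs are concatenated, labelled by model of origin.
Synthetic cells whose position contradicts their model label (their
nearest real reference-modality cells vote for a different batch) can then be
removed by `filter_by_model_label()` — consistency filtering that discards
cells a batch-specific model placed in another batch's territory.

## Using the bridge

The generator emits embeddings, not features. `fit_feature_regressor()` /
`reconstruct_features()` impute features by kNN regression (k = 2, Euclidean,
unweighted mean), so every imputed value lies within the convex hull of
observed values. `transfer_labels()` propagates labels source → synthetic →
target by two rounds of kNN majority voting (k = 15 per stage, matching
common kNN-graph sizes; ties break to the lexicographically smallest label,
making transfer deterministic). Per-stage agreement fractions are recorded and
multiplied into a per-cell confidence. The two-stage vote replaces
graph-partition label transfer used by some pipelines; it is self-contained
and deterministic, and the only information either scheme actually uses here
is embedding proximity — no equivalence with marginal-based assignment is
claimed.

## Evaluation suite

* **AMI** — mutual information of two labelings, chance-corrected with the
  exact hypergeometric expectation and arithmetic-mean normalization. Boundary
  conventions: two trivial partitions → 1, one trivial partition → 0.
* **Homogeneity / completeness / V-measure** — the entropy-based definitions;
  V is their harmonic mean.
* **LISI** — for each cell, Gaussian kernel weights over its 3 x perplexity
  nearest neighbours, bandwidth fitted by bisection to the target perplexity
  (tolerance 1e-5 on the entropy, at most 50 steps); the inverse Simpson index
  of the label mixture, from 1 (one label only) to the number of labels
  (perfect mixing). Squared Euclidean distances; the cell itself is excluded.
* **Marker ranking** — per group, two-sided Wilcoxon rank-sum versus the rest
  (normal approximation with tie and continuity corrections, cross-checked
  against `stats::wilcox.test`), Benjamini–Hochberg adjustment within group,
  log2 fold change of group versus rest means with pseudocount 1e-9 (means
  clamped at zero for noisy near-zero features).
* **Preranked GSEA** — classic weighted Kolmogorov–Smirnov running sum with
  weight |metric|^1; ES is the extremum of the running sum; the null comes
  from random same-size sets (default 1000 draws, seeded); NES divides ES by
  the mean |null ES| of matching sign. `fgsea` serves as an independent
  cross-check of the ES in the tests, never as the implementation.
* **Cell-type accuracy** — cells split 70:30 (stratified by type, so small
  types survive at fixture scale; plain uniform splitting risks empty groups),
  marker sets built on the test split (adjusted p < 5e-3, top 100 features for
  expression-like or 500 for region-like modalities, decreasing fold change),
  rankings on the training split, and a cell-type × cell-type matrix of NES
  values. Columns are scaled by their absolute maxima (entries in [-1, 1];
  NaN → 0), positive/negative diagonal mass counts as TP/FN, positive/negative
  off-diagonal mass as FP/TN, and weighted accuracy is
  (TP + TN)/(TP + TN + FP + FN). Negative entries contribute their absolute
  value to the FN/TN sums — signs mark the outcome class, magnitudes the
  weight; the unweighted variant replaces scaled values by their signs.

## The simulator

`generate_study()` draws K latent populations (isotropic Gaussians in
`d_latent` dimensions) and renders each modality as `latent %*% load + noise`;
features are `softplus(embedding %*% feature_map) + noise` (softplus keeps
them non-negative like normalized expression; a linear option exists for
exactness tests). Paired studies reuse one latent draw across modalities;
unpaired studies draw independent cells from the same population. Batch
structure adds latent-space offsets. Ground-truth population labels ride along
on every view, so AMI against truth is always computable, and the same seed
reproduces a study byte for byte.

The standard fixture is K = 3, d_latent = 8, C = 10, M = 2, 3000 cells per
modality, within-population sd 1, embedding noise sd 0.3, with the three
population centres arranged along a differentiation-like axis with mild
lateral offsets, unequal spacings (~4–4.7 sd between neighbours) and unequal
proportions (0.45/0.30/0.25) — clearly distinct populations at a size where
adversarial training completes in minutes on one CPU. The geometry honours
the operating assumptions of the eigenmap pre-matching. First, connectivity:
with fully disconnected equal-size clusters the nontrivial Laplacian
eigenspace is degenerate (inter-cluster affinities underflow far below the
uniform regularizer) and each modality's eigenmap orders the clusters
arbitrarily, so no pre-matching scheme could align them; real embeddings
have connected neighbour graphs. Second, one-axis structure: the ordering
keeps a single eigenvector component, which cannot distinguish clusters
placed symmetrically about the leading axis — matching presumes the coarse
population order is carried by one axis, as in a differentiation continuum.
Third, asymmetry: the unequal spacings and proportions, typical of real
tissue composition, give the eigenmap value distribution a geometric (rather
than sampling-noise) asymmetry, which is what the cross-modality orientation
alignment keys on; a perfectly symmetric arrangement would leave the
orientation statistically undetermined for any method that sees each
modality's cells separately. What the simulator does
**not** emulate: count-level noise (negative binomial, dropout), library-size
effects, doublets, or realistic feature correlation structure. Passing tests
demonstrate that the machinery recovers geometry and pairing under a faithful
low-dimensional model of population structure — not that it is robust to raw
count pathology, which upstream normalization and embedding pipelines are
assumed to handle.

## Numerical choices and degenerate inputs

* Eigenvector sign: canonicalized as above; ordering ties break by cell index.
* Candidate score ties: lowest candidate index wins.
* kNN majority ties: lexicographically smallest label.
* Zero-variance candidate batches score 0; empty GSEA intersections yield NaN
  NES, imputed as 0 in the confusion matrix.
* A modality with fewer than N cells refuses to train; semisupervised batches
  below N are skipped with a warning.
* Graph weights: Gaussian affinities with per-cell bandwidth set to the k-th
  neighbour distance; directed inputs are symmetrized by maximum weight with a
  warning.
* Problem sizes in the tests: gradient checks on M = 2, C = 3 networks;
  training properties on the 3000-cell fixture with reduced filters (64, 32)
  and N = 64 for 1500 generator steps; metric oracles on ≤ 30-cell instances.

## Known limitations

* Adversarial training quality at desk scale is deliberately modest; the
  mixing scores it reaches on the fixture are far from what long training at
  full width would achieve.
* The eigenmap ordering assumes the kNN graph reflects meaningful local
  structure; on near-random graphs the pre-matching degenerates gracefully to
  random matching but adds nothing.
* LISI values depend on the perplexity and on embedding scale homogeneity
  across the joint dataset; they are comparable only within one construction.
* The h5ad writer covers the slots this tool uses (X, obs, var, obsm, obsp
  CSR, uns strings) — it is not a general AnnData serializer.
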