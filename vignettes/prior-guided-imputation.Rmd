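---
title: "Prior-guided factorization imputation: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior-guided factorization imputation: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scprior)
```

## The problem

A single-cell RNA-seq count matrix $X \in \mathbb{N}_0^{n \times m}$ ($n$
cells, $m$ genes) is mostly zeros. Some zeros are biological — the gene is
genuinely silent in that cell — and some are technical dropout: the
transcript was present but not captured or amplified. Downstream analyses
(clustering, marker ranking, co-expression, trajectory inference) degrade
when technical zeros are left in place, and degrade differently when every
zero is "corrected" indiscriminately. The position this package takes is
that whether a zero should be filled is decided by the cell's position in a
latent similarity space, not by the zero itself: if cells similar to cell
$i$ stably express gene $j$, an observed zero at $(i,j)$ is probably
technical; if similar cells express it weakly or erratically, the zero is
probably real and should survive imputation.

## The model

**Size factors.** Depth is technical, so it is handled at the observation
layer only: $s_i = \sum_j X_{ij} / \mathrm{median}_r \sum_j X_{rj}$. Under
Poisson thinning (each molecule captured independently with probability
$p_i$), observed counts are Poisson with mean $p_i \lambda_{ij}$, so one
multiplicative per-cell factor is the right correction and the biological
mean never absorbs depth.

**Factorization.** Two unconstrained matrices $W \in \mathbb{R}^{n\times k}$
and $H \in \mathbb{R}^{k\times m}$ are made admissible by
$\hat W = \mathrm{ReLU}(W)$, $\hat H = \mathrm{ReLU}(H)$ and a row-wise
softmax, giving each cell a probability distribution over $k$ latent
modules. With cell-type labels available, the one-hot encoding
$P \in \{0,1\}^{n\times k}$ and the type-wise mean profiles
$H_{\mathrm{prior}}$ (arithmetic means of raw count rows per type) are
blended in with equal weight:

$$W^+ = \tfrac12\left(P + \mathrm{softmax}(\hat W)\right), \qquad
  H^+ = \tfrac12\left(H_{\mathrm{prior}} + \hat H\right),$$

for labeled cells; unlabeled cells keep their softmax row, and without any
labels the model runs unsupervised ($W^+ = \mathrm{softmax}(\hat W)$,
$H^+ = \hat H$). The biological mean is $\mu = W^+ H^+$ and the
observation-scale reconstruction is $\mu^{\mathrm{adj}}_{ij} = s_i\,
\kappa_{j,b(i)}\, \mu_{ij}$, where $\kappa$ is a per-gene per-batch factor
($\kappa \equiv 1$ without batches). Observation noise is never sampled:
the imputed value is a conditional mean, and stochasticity lives in the
likelihood term below.

**The four loss terms.** Training minimizes
$\mathcal{L} = \lambda_{\mathrm{nmf}}\mathcal{L}_{\mathrm{nmf}} +
\lambda_{\mathrm{zinb}}\mathcal{L}_{\mathrm{zinb}} +
\lambda_{\mathrm{z}}\mathcal{L}_{\mathrm{z}} +
\lambda_{\mathrm{class}}\mathcal{L}_{\mathrm{class}}$ with every
$\lambda \in \{0,1\}$ — the weights are switches, not tuning dials:

* $\mathcal{L}_{\mathrm{nmf}} = \lVert X - \mu^{\mathrm{adj}}
  \rVert_F / (nm)$ — the mean Frobenius *norm* (not its square), a
  symmetric quadratic pull toward the observed counts.
* $\mathcal{L}_{\mathrm{zinb}}$ — the mean negative log-likelihood of a
  zero-inflated negative binomial with mean $\mu^{\mathrm{adj}}$ (clipped
  below at $10^{-8}$, where the PMF is otherwise undefined), one free
  dropout logit per gene broadcast over cells, and a single shared
  dispersion $\theta = \mathrm{softplus}(\cdot) + 10^{-4}$. This aligns the
  zero fraction and mean–variance behaviour of the reconstruction with what
  count data actually look like, and punishes over-smoothed imputations.
* $\mathcal{L}_{\mathrm{z}}$ — the mean squared difference between row-wise
  z-scores (population standard deviation, divisor $m$, plus
  $\epsilon = 10^{-8}$) of $X$ and of $\mu$. Z-scoring removes per-cell
  scale and offset, so this term preserves each cell's relative expression
  geometry; it is exactly invariant to the size factors, which the test
  suite asserts.
* $\mathcal{L}_{\mathrm{class}}$ — cross-entropy of a linear softmax probe
  on $W^+$, averaged over labeled cells. A biologically meaningful module
  coordinate should make cell identity linearly decodable; this term both
  tests and enforces that, and is switched off when no labels exist.

**Dropout parameterization.** The structural-zero probability is
$\pi_{ij} = \sigma(\rho_j)$: one logit per gene. Dropout propensity is
predominantly gene-driven (capture efficiency scales with expression and
transcript properties), and $O(m)$ parameters keep the model desk-scale. A
per-entry $\pi$ would be unidentifiable from one observation per entry.

**Batch factors.** The trainable set is $\{W, H, \rho, \theta,
w_c, b\}$; $\kappa$ is deliberately not trained. It is estimated once by
moments — per gene, the batch mean of depth-normalized counts on the log1p
scale, centered per gene across batches — and held fixed. The centering is
the identifiability constraint: the geometric mean of $\kappa$ across
batches is 1 for every gene, so batch factors cannot absorb biological mean
expression. A trained $\kappa$ would compete with $H$ for the same
variance; a moment estimate is stable and transparent.

**Optimization and stopping.** Full-batch Adam (bias-corrected moments,
$\epsilon_{\mathrm{adam}} = 10^{-8}$) with the step schedule
$\eta_t = \eta_0 \gamma^{\lfloor t/T \rfloor}$. Defaults: $\eta_0 = 0.01$,
$\gamma = 0.95$, $T = 200$, at most 2000 epochs. Training stops when the
relative change of the objective stays below
$\epsilon_{\mathrm{loss}} = 0.001$ for 10 consecutive epochs (`patience`);
a previous loss below $10^{-12}$ counts as converged. Full-batch is the
right regime here: the stopping rule is defined on the full objective, and
desk-scale problems fit comfortably in memory. All gradients are analytic
and verified against central finite differences to $10^{-4}$ relative
error in the test suite; fits are bitwise reproducible given the seed.

**Imputation rule.** Only zeros are replaced:
$\tilde X_{ij} = X_{ij}$ if $X_{ij} > 0$, else $\mu^{\mathrm{adj}}_{ij}$.
Observed nonzero counts are treated as reliable measurements and survive
bit for bit. Imputed entries are reported on the observation scale
(including $s_i$ and $\kappa$) so they are commensurate with the retained
raw counts of the same cell; no rounding and no small-value thresholding is
applied. Whether to post-filter tiny imputed values is left to the user.

## What the simulator emulates

`simulate_counts()` realizes the generative picture the model assumes:
types drawn multinomially, per-cell depth log-normal
($\sigma_{\log} = 0.3$), a shared log-normal gene baseline with an
exclusive marker block per type, negative binomial counts
(Gamma–Poisson, shared dispersion), and independent per-entry Bernoulli
dropout. Defaults are the conditions the recovery experiments use: 300
cells, 150 genes, 3 types, $\theta_{\mathrm{true}} = 2$, dropout rate 0.5
at the median log mean.

Two defaults deserve a word:

* *Mean-dependent dropout.* The default dropout probability decreases
  logistically in log mean expression (rate 0.5 at the median log-mean,
  slope 1 per log unit), with a constant-rate option. Mean dependence is
  what makes a technical zero statistically distinguishable from a
  biological one — the premise of the whole method — so a fixture without
  it would not probe the interesting regime.
* *Marker fold change 3.* Each type up-regulates its exclusive marker block
  3-fold. This is a subtle-subtype regime: with strong (say 8-fold)
  markers, k-means on the raw dropped-out matrix is already essentially
  perfect and dropout costs nothing, so the fixture would have nothing to
  recover. At 3-fold, dropout visibly degrades raw clustering, which is the
  phenomenon imputation is supposed to repair.

One pragmatic guard: a simulated cell that loses *every* count to dropout
would violate the loader invariant (size factors divide by row totals), so
its single largest pre-dropout entry is restored and unmasked. At the
default settings this affects at most a handful of cells.

What the simulator does **not** emulate: ambient RNA, doublets, gene–gene
correlation beyond type structure, per-cell dropout covariates, batch
chemistry differences (batches enter only as a per-gene multiplicative
factor), or any real dataset's empirical distributions. Passing recovery
tests on these fixtures therefore shows the estimator is correct under its
own assumptions — not that it wins on any particular tissue.

## Numerical choices and degenerate inputs

* Cells with zero total count are rejected at load, naming the cell: a zero
  row makes $s_i = 0$ and the depth-adjusted reconstruction degenerate.
  Failing fast beats emitting NaNs downstream.
* ReLU subgradient at 0 is taken as 0; initialization (uniform(0, 0.1))
  keeps parameters strictly positive so early training never sits on the
  kink.
* The likelihood mean clip at $10^{-8}$ kills the mean-gradient at clipped
  entries; well-fit entries are unaffected.
* $k \ge C$ is required with labels; $k > C$ adds "anonymous" modules whose
  prior columns are zero and whose prototype rows are the global mean.
  Types with no labeled cell also fall back to the global mean row.
* Prototype profiles are computed on raw counts exactly as defined. Under
  partial labels, only labeled cells contribute; unlabeled cells are
  excluded from the shrinkage and the classification loss, degrading
  gracefully to the unsupervised forward.
* Plateau ratios with $|\mathcal{L}(t-1)| < 10^{-12}$ are treated as 0, so
  an identically zero objective (all switches off) stops at epoch
  `patience + 1`.
* The z-score denominator guard $\epsilon = 10^{-8}$ makes constant rows
  map to zero vectors instead of NaN.

## Evaluation suite

The metric functions take partitions, scores, or embeddings as plain
inputs, so any external clustering can be scored. Conventions: ARI uses the
hypergeometric chance correction; clustering accuracy maximizes the matched
fraction over one-to-one cluster-to-class assignments (a hand-written
$O(n^3)$ Hungarian solver, verified against exhaustive permutation); macro
F1 maps clusters to classes the same way, with empty-denominator classes
contributing 0; macro AUC uses tie-averaged rank statistics; the silhouette
uses Euclidean distance with singletons scored 0; the cross-boundary
direction score averages cosines per boundary cell, then over boundary
cells, and reports "no boundary" as missing rather than 0. The
correlation-structure agreement procedure subsamples 20% of cells 50 times
by default and reports both the upper-triangle Pearson correlation and the
Frobenius distance to a reference gene–gene correlation matrix.

The clustering *helper* (`kmeans_partition()`) is deliberately generic
plumbing: library-size normalization, log1p, seeded `stats::kmeans`. Depth
is a technical covariate, so it is removed before clustering — on imputed
matrices especially, where the smooth depth-scaled fill would otherwise
hand k-means a depth gradient as its strongest direction. The
representation used is recorded in the evaluation table, since geometry
metrics are only comparable within a stated representation.

## Problem sizes used by the checks

The recovery experiments fit 300 cells x 150 genes, 3 types, over three
seeds; at these sizes a fit plateaus after roughly 160–200 epochs and takes
a few seconds, and the 16-subset switch ablation over three seeds completes
in about two minutes. These sizes were chosen as the smallest at which the
clustering and recovery effects are comfortably visible above seed noise.

## Known limitations

* The supervised mode shrinks toward the labels it is given; with heavily
  corrupted labels the prior pulls the wrong way, and the label-noise
  protocol exists precisely to quantify that degradation.
* A single shared dispersion is a deliberate simplification; strongly
  gene-specific overdispersion is absorbed partly by the dropout logits.
* The untrained supervised forward already contains the label prior, so on
  easy fixtures the all-switches-off baseline clusters well; the loss terms
  earn their keep on geometry (silhouette) and mean recovery rather than on
  saturated partition metrics.
* No learned soft memberships: a user-supplied row-stochastic `P` is
  accepted, but the package never infers one.
* Imputed values are conditional means; no per-entry uncertainty is
  reported.
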