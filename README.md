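# scprior

Prior-guided nonnegative factorization imputation for single-cell RNA-seq
count matrices.

## What problem this solves

scRNA-seq count matrices are dominated by zeros, a mixture of genuine
biological silence and technical dropout (capture/amplification failure).
`scprior` decides which zeros to fill from a latent similarity space rather
than from the zeros themselves: it factorizes the counts into a
row-stochastic cell-by-module matrix and a module-by-gene profile matrix,
and — when cell-type labels are available — shrinks the cell factor toward
the one-hot label encoding and the gene factor toward type-wise prototype
profiles:

    W+ = (P + softmax(ReLU(W))) / 2        H+ = (H_prior + ReLU(H)) / 2
    mu = W+ H+                             mu_adj[i,j] = s_i * kappa[j,b(i)] * mu[i,j]

with per-cell size factors `s_i` (row total over median row total) and
optional per-gene batch factors `kappa`. Training minimizes a four-term
switched objective by full-batch Adam:

* mean Frobenius reconstruction error `||X − mu_adj||_F / (nm)`,
* a zero-inflated negative binomial negative log-likelihood (per-gene
  dropout logits, shared dispersion),
* a per-cell z-score consistency loss that preserves relative expression
  geometry,
* a linear-probe cross-entropy that keeps cell identity linearly decodable
  from the embedding,

each gated by a binary switch. Training stops when the objective plateaus
(relative change < 0.001 for 10 consecutive epochs). Imputation replaces
**only the observed zeros** with `mu_adj`; every nonzero count is preserved
exactly. Without labels the same machinery runs fully unsupervised.

The package also ships a clustered Gamma–Poisson simulator with Bernoulli
dropout and known ground truth, label-degradation protocols (subsampling
and noise injection), and an evaluation suite: ARI, Hungarian-matched
accuracy, macro F1, macro one-vs-rest AUC, silhouette, cross-boundary
direction correctness (CBDir), gene-level Pearson correlation, marker
leakage ratio, and correlation-structure agreement under cell subsampling.

Intended users: anyone benchmarking or applying label-aware imputation on
count matrices at desk scale, and anyone who needs the metric suite with
exactly stated conventions.

## Worked example

```r
library(scprior)

sim <- simulate_counts(simulation_config(seed = 1))   # 300 cells x 150 genes, 3 types
fit <- fit_factor_model(sim$X, sim$labels, config = training_config(seed = 1))
fit
#> Prior-guided factorization fit (prior mode)
#>   cells: 300  genes: 150  modules: 3
#>   stopped at epoch 163 ( plateau )
#>   final losses: total=2.6545 nmf=0.014799 zinb=1.4969 zscore=0.9271 class=0.21571

imp <- impute_zeros(sim$X, fit)
sum(sim$X == 0); sum(imp$imputed == 0)
#> [1] 27008
#> [1] 0

evaluate_imputation(sim$X, imp$imputed, truth = sim$labels$label, cluster_k = 3)
#>                metric value  status                        params
#> 1   gene_pearson_mean 0.953      ok                   defined=150
#> 2                 ari 1.000      ok
#> 3 clustering_accuracy 1.000      ok
#> 4            macro_f1 1.000      ok
#> 5     silhouette_mean 0.103      ok log1p depth-normalized counts
#> 6       macro_auc_ovr    NA skipped                  needs scores
#> 7               cbdir    NA skipped               needs embedding

cor(log1p(fit$output$mu_adjusted[sim$dropout_mask]),
    log1p(sim$mu_true[sim$dropout_mask]))
#> [1] 0.9240
```

Reading the numbers: all 27,008 zeros were replaced by model means (none of
them landed at exactly zero), the retained nonzero counts are untouched
(hence the gene-level Pearson of 0.953 between raw and imputed), seeded
k-means on the imputed matrix recovers the three simulated types perfectly
(ARI/accuracy/F1 = 1), and the model means at the entries that were zeroed
by simulated dropout correlate at r = 0.924 (log1p scale) with the true
generating means. `tidy(fit)` / `glance(fit)` / `autoplot(fit)` give the
training trace in long form, a one-row fit summary, and a loss-curve plot.

A command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "scprior.R", package="scprior"))') \
  impute --counts counts.csv --labels labels.tsv --seed 7 --out-dir out/
```

Subcommands: `impute`, `simulate`, `ablate` (all 16 loss-switch subsets),
`evaluate`. Every run writes a JSON manifest sufficient to reproduce its
outputs bitwise.

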