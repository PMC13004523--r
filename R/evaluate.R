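#' Seeded k-means partition of an expression matrix
#'
#' Generic clustering plumbing used by the evaluation and ablation commands:
#' library-size-normalizes each cell (row total over median row total —
#' depth is a technical covariate, not cluster structure), log1p-transforms
#' (counts and imputed values are heavy-tailed), and runs `stats::kmeans`
#' with a fixed seed and multiple restarts. Not part of the model itself —
#' any external partition can be passed to the metric functions directly.
#'
#' @param M Cells x genes matrix.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param nstart Restarts (default 10).
#' @param normalize Divide each row by its size factor first (default TRUE).
#' @param log1p Apply `log1p` before clustering (default TRUE).
#' @return Integer cluster assignment per cell.
#' @export
kmeans_partition <- function(M, k, seed = 1L, nstart = 10, normalize = TRUE,
                             log1p = TRUE) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  Z <- if (normalize) .depth_normalize(M) else M
  if (log1p) Z <- log1p(Z)
  stats::kmeans(Z, centers = k, nstart = nstart, iter.max = 50)$cluster
}

.depth_normalize <- function(M) {
  tot <- rowSums(M)
  tot[tot == 0] <- 1
  M / (tot / stats::median(tot))
}

#' Metrics table for an imputation run
#'
#' Computes every metric the supplied inputs allow and reports the rest as
#' skipped: gene-level Pearson summary always; ARI, Hungarian accuracy and
#' macro F1 when a predicted partition is given (or computed via
#' [kmeans_partition()] when `cluster_k` is set); silhouette on the imputed
#' matrix under the truth partition; macro AUC when per-class scores are
#' given; CBDir when an embedding is given.
#'
#' @param raw Raw count matrix.
#' @param imputed Imputed matrix of the same shape.
#' @param truth Ground-truth labels per cell (vector), or NULL.
#' @param pred Optional predicted partition.
#' @param cluster_k If `pred` is NULL, cluster the imputed matrix into this
#'   many groups first (NULL skips external metrics).
#' @param scores Optional per-class score matrix for AUC.
#' @param embedding Optional list with `coords`, `velocity`, `neighbors`,
#'   `source`, `target` for CBDir.
#' @param representation Character note recorded alongside geometry metrics
#'   (which space silhouette/clustering used); default
#'   "log1p depth-normalized counts".
#' @param seed Seed for the clustering helper.
#' @return Tibble: `metric`, `value`, `status` (`"ok"`/`"skipped"`),
#'   `params`.
#' @export
evaluate_imputation <- function(raw, imputed, truth = NULL, pred = NULL,
                                cluster_k = NULL, scores = NULL,
                                embedding = NULL,
                                representation = "log1p depth-normalized counts",
                                seed = 1L) {
  rows <- list()
  add <- function(metric, value, status = "ok", params = "") {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      metric = metric, value = value, status = status, params = params)
  }
  gp <- gene_pearson_summary(gene_pearson(raw, imputed))
  add("gene_pearson_mean", gp$mean_r, params = paste0("defined=", gp$n_defined))

  if (is.null(pred) && !is.null(cluster_k)) {
    pred <- kmeans_partition(imputed, cluster_k, seed = seed)
  }
  if (!is.null(truth) && !is.null(pred)) {
    add("ari", adjusted_rand_index(truth, pred))
    add("clustering_accuracy", clustering_accuracy(truth, pred))
    add("macro_f1", macro_f1(truth, pred))
  } else {
    add("ari", NA_real_, "skipped", "needs truth+pred")
    add("clustering_accuracy", NA_real_, "skipped", "needs truth+pred")
    add("macro_f1", NA_real_, "skipped", "needs truth+pred")
  }
  if (!is.null(truth) && length(unique(truth)) >= 2) {
    add("silhouette_mean",
        silhouette_mean(log1p(.depth_normalize(imputed)), truth),
        params = representation)
  } else {
    add("silhouette_mean", NA_real_, "skipped", "needs >=2 truth classes")
  }
  if (!is.null(truth) && !is.null(scores)) {
    add("macro_auc_ovr", macro_auc_ovr(truth, scores))
  } else {
    add("macro_auc_ovr", NA_real_, "skipped", "needs scores")
  }
  if (!is.null(embedding)) {
    val <- cbdir(embedding$coords, embedding$velocity, embedding$neighbors,
                 truth, embedding$source, embedding$target)
    add("cbdir", val, if (is.na(val)) "skipped" else "ok",
        paste0(embedding$source, "->", embedding$target))
  } else {
    add("cbdir", NA_real_, "skipped", "needs embedding")
  }
  do.call(rbind, rows)
}

#' Loss-switch ablation over all 16 subsets
#'
#' Fits the model once per subset of the four loss switches (and per seed),
#' imputes, clusters the imputed matrix with seeded k-means, and scores ARI
#' against the truth labels and mean silhouette under the k-means partition.
#' Subsets containing the classification term require labels; the all-zeros
#' subset is the untrained baseline (initialization only).
#'
#' @param X Count matrix.
#' @param labels Truth label tibble (used as prior and for scoring).
#' @param k Number of modules/clusters.
#' @param seeds Integer seeds to average over (default 1).
#' @param config Base [training_config()]; its switches are overridden per
#'   subset and its seed per replicate.
#' @return Tibble with 16 rows: `bitmask` (`lambda_nmf lambda_zinb
#'   lambda_zscore lambda_class` as a 4-character string), the four switch
#'   columns, `mean_ari`, `mean_silhouette`, `mean_epochs`.
#' @export
run_ablation <- function(X, labels, k = NULL, seeds = 1L,
                         config = training_config()) {
  truth <- labels$label
  rows <- vector("list", 16)
  for (mask in 0:15) {
    lam <- c(nmf = bitwAnd(mask, 8L) > 0, zinb = bitwAnd(mask, 4L) > 0,
             zscore = bitwAnd(mask, 2L) > 0, class_ = bitwAnd(mask, 1L) > 0)
    aris <- sils <- eps <- numeric(length(seeds))
    for (si in seq_along(seeds)) {
      cfg <- config
      cfg$weights <- loss_weights(nmf = as.numeric(lam[["nmf"]]),
                                  zinb = as.numeric(lam[["zinb"]]),
                                  zscore = as.numeric(lam[["zscore"]]),
                                  class_ = as.numeric(lam[["class_"]]))
      cfg$seed <- as.integer(seeds[si])
      fit <- fit_factor_model(X, labels, k = k, config = cfg, mode = "prior")
      imp <- impute_zeros(X, fit)
      part <- kmeans_partition(imp$imputed, fit$k, seed = seeds[si])
      aris[si] <- adjusted_rand_index(truth, part)
      sils[si] <- silhouette_mean(log1p(.depth_normalize(imp$imputed)), part)
      eps[si] <- fit$stop_epoch
    }
    rows[[mask + 1]] <- tibble::tibble(
      bitmask = paste(as.integer(lam), collapse = ""),
      lambda_nmf = as.integer(lam[["nmf"]]),
      lambda_zinb = as.integer(lam[["zinb"]]),
      lambda_zscore = as.integer(lam[["zscore"]]),
      lambda_class = as.integer(lam[["class_"]]),
      mean_ari = mean(aris), mean_silhouette = mean(sils),
      mean_epochs = mean(eps))
  }
  do.call(rbind, rows)
}
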