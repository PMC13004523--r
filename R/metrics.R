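# Evaluation suite: partition agreement, embedding geometry, and
# imputation-fidelity metrics.

.check_partitions <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, corrected for chance via
#' the hypergeometric expectation of the contingency-table index. Invariant
#' to relabeling; 1 for identical partitions, around 0 for independent ones.
#'
#' @param a,b Cluster assignments (any atomic labels), equal length.
#' @return Scalar in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  .check_partitions(a, b)
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(tab)
  row_c <- sum_comb(rowSums(tab))
  col_c <- sum_comb(colSums(tab))
  expected <- row_c * col_c / choose(n, 2)
  max_idx <- (row_c + col_c) / 2
  if (max_idx == expected) return(0)
  (idx - expected) / (max_idx - expected)
}

#' Hungarian-matched clustering accuracy
#'
#' Fraction of correctly assigned cells after the optimal one-to-one
#' cluster-to-class matching (maximum-weight matching on the contingency
#' table, solved by the Hungarian algorithm).
#'
#' @param truth,pred Cluster assignments, equal length.
#' @return Scalar in [0, 1].
#' @export
clustering_accuracy <- function(truth, pred) {
  .check_partitions(truth, pred)
  tab <- table(pred, truth)       # rows: predicted clusters, cols: classes
  assign <- solve_assignment(-tab)
  matched <- sum(tab[cbind(which(assign > 0), assign[assign > 0])])
  matched / length(truth)
}

#' Macro-averaged F1 after cluster-to-class mapping
#'
#' Per-class precision, recall and F1 on the mapped predictions, averaged
#' with equal class weight; classes with an empty precision or recall
#' denominator (or zero precision + recall) contribute F1 = 0.
#'
#' @param truth,pred Cluster assignments, equal length.
#' @param mapping `"hungarian"` (map predicted clusters to classes first,
#'   default) or `"identity"` (labels already share a vocabulary).
#' @return Scalar in [0, 1].
#' @export
macro_f1 <- function(truth, pred, mapping = c("hungarian", "identity")) {
  mapping <- match.arg(mapping)
  .check_partitions(truth, pred)
  truth <- as.character(truth)
  pred <- as.character(pred)
  if (mapping == "hungarian") {
    classes <- unique(truth)
    clusters <- unique(pred)
    tab <- table(factor(pred, clusters), factor(truth, classes))
    assign <- solve_assignment(-tab)
    mapped <- rep("(unmatched)", length(pred))
    for (r in seq_along(clusters)) {
      if (assign[r] > 0) mapped[pred == clusters[r]] <- classes[assign[r]]
    }
    pred <- mapped
  }
  classes <- unique(truth)
  f1s <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }, numeric(1))
  mean(f1s)
}

#' Macro one-vs-rest ROC AUC
#'
#' Per-class AUC from the rank statistic (Mann-Whitney with tie-averaged
#' ranks) of the class score column against the one-vs-rest truth, averaged
#' over classes present in the truth; classes with zero positives or zero
#' negatives are skipped with a warning.
#'
#' @param truth Class assignments.
#' @param scores Numeric matrix, one column per class, column names giving
#'   the class vocabulary.
#' @return Scalar in [0, 1].
#' @export
macro_auc_ovr <- function(truth, scores) {
  truth <- as.character(truth)
  if (nrow(scores) != length(truth)) stop("scores/truth length mismatch")
  classes <- intersect(colnames(scores), unique(truth))
  if (length(classes) == 0) stop("no truth class present in score columns")
  aucs <- numeric(0)
  for (cl in classes) {
    pos <- truth == cl
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) {
      warning("class '", cl, "' has no positives or no negatives; skipped")
      next
    }
    r <- rank(scores[, cl])
    aucs <- c(aucs, (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0))
  }
  mean(aucs)
}

#' Mean silhouette coefficient
#'
#' For each cell, s(i) = (b(i) - a(i)) / max(a(i), b(i)) with a(i) the mean
#' Euclidean distance to its own cluster (excluding itself) and b(i) the
#' minimum over other clusters of the mean distance; singletons score 0.
#' Returns the mean over all cells.
#'
#' @param X Numeric matrix (cells x features) or a `dist` object.
#' @param labels Cluster assignment per cell; at least 2 clusters.
#' @return Scalar in [-1, 1].
#' @export
silhouette_mean <- function(X, labels) {
  labels <- as.character(labels)
  D <- if (inherits(X, "dist")) as.matrix(X) else as.matrix(stats::dist(X))
  n <- nrow(D)
  if (length(labels) != n) stop("labels/matrix length mismatch")
  clusters <- unique(labels)
  if (length(clusters) < 2) stop("silhouette requires at least 2 clusters")
  sizes <- table(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    if (sizes[[own]] == 1) { s[i] <- 0; next }
    a <- sum(D[i, labels == own]) / (sizes[[own]] - 1)
    b <- min(vapply(setdiff(clusters, own),
                    function(cl) mean(D[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Cross-boundary direction correctness (CBDir)
#'
#' Scores whether inferred velocities at the boundary between a source and a
#' target cluster point toward the target. Boundary cells of the source are
#' its cells with at least one graph neighbor in the target; for each such
#' cell the cosine between its velocity and the displacement to each target
#' neighbor is averaged, and the score is the mean over boundary cells
#' (two-level averaging).
#'
#' @param coords Cells x d embedding coordinates.
#' @param velocity Cells x d velocity vectors.
#' @param neighbors List of integer neighbor indices per cell (no
#'   self-loops).
#' @param labels Cluster assignment per cell (ground truth).
#' @param source,target Cluster ids of the transition to score.
#' @return Scalar in [-1, 1], or `NA` when the source has no boundary cell
#'   toward the target.
#' @export
cbdir <- function(coords, velocity, neighbors, labels, source, target) {
  labels <- as.character(labels)
  n <- nrow(coords)
  stopifnot(length(neighbors) == n, nrow(velocity) == n)
  src_cells <- which(labels == source)
  per_cell <- numeric(0)
  for (c_i in src_cells) {
    nb <- neighbors[[c_i]]
    tgt_nb <- nb[labels[nb] == target]
    if (length(tgt_nb) == 0) next
    v <- velocity[c_i, ]
    cosines <- vapply(tgt_nb, function(cp) {
      d <- coords[cp, ] - coords[c_i, ]
      sum(v * d) / (sqrt(sum(v^2)) * sqrt(sum(d^2)))
    }, numeric(1))
    per_cell <- c(per_cell, mean(cosines))
  }
  if (length(per_cell) == 0) return(NA_real_)
  mean(per_cell)
}

#' Gene-level Pearson correlation between raw and imputed matrices
#'
#' For each gene, the Pearson correlation between its raw and imputed
#' expression vectors across cells; genes with zero variance in either
#' vector are undefined and excluded from the summary.
#'
#' @param raw,imputed Matrices of identical shape (cells x genes).
#' @return A tibble with one row per gene (`gene`, `r`) plus attributes; use
#'   [gene_pearson_summary()] for the aggregate.
#' @export
gene_pearson <- function(raw, imputed) {
  if (!all(dim(raw) == dim(imputed))) stop("shape mismatch in gene_pearson")
  r <- vapply(seq_len(ncol(raw)), function(j) {
    x <- raw[, j]; y <- imputed[, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  tibble::tibble(gene = colnames(raw), r = r)
}

#' Summary of gene-level Pearson correlations
#'
#' @param tab Output of [gene_pearson()].
#' @return One-row tibble: `mean_r` over defined genes, `n_defined`,
#'   `n_excluded`.
#' @export
gene_pearson_summary <- function(tab) {
  tibble::tibble(mean_r = mean(tab$r, na.rm = TRUE),
                 n_defined = sum(!is.na(tab$r)),
                 n_excluded = sum(is.na(tab$r)))
}

#' Marker leakage ratio
#'
#' Mean expression of a marker gene set in cells of the wrong type divided
#' by its mean in cells of the correct type. Values near 0 mean no spurious
#' marker signal was imputed into the wrong population; 1 means markers leak
#' fully.
#'
#' @param M Expression matrix (cells x genes) with dimnames.
#' @param markers Marker gene ids.
#' @param correct_cells,wrong_cells Disjoint, nonempty cell id sets.
#' @return Scalar ratio (lower is better).
#' @export
leakage_ratio <- function(M, markers, correct_cells, wrong_cells) {
  if (length(intersect(correct_cells, wrong_cells)) > 0) {
    stop("correct and wrong cell sets must be disjoint")
  }
  if (!all(markers %in% colnames(M))) stop("unknown marker gene id")
  if (!all(c(correct_cells, wrong_cells) %in% rownames(M))) stop("unknown cell id")
  num <- mean(M[wrong_cells, markers, drop = FALSE])
  den <- mean(M[correct_cells, markers, drop = FALSE])
  if (den == 0) stop("leakage ratio undefined: zero marker expression in correct cells")
  num / den
}

#' Correlation-structure agreement under cell subsampling
#'
#' Repeatedly subsamples a fraction of cells without replacement, computes
#' the gene-gene Pearson correlation matrix of the subsample, and compares
#' it to a reference correlation matrix by (a) the Pearson correlation of
#' the upper-triangular entries and (b) the Frobenius norm of the
#' difference.
#'
#' @param ref_corr Reference gene-gene correlation matrix (symmetric, unit
#'   diagonal).
#' @param M Expression matrix (cells x genes).
#' @param subsample_fraction Fraction of cells per iteration (default 0.2).
#' @param iterations Number of subsampling iterations (default 50).
#' @param seed Integer seed.
#' @return Tibble with one row per iteration: `iteration`, `similarity`
#'   (upper-triangle Pearson), `distance` (Frobenius norm).
#' @export
correlation_structure_agreement <- function(ref_corr, M,
                                            subsample_fraction = 0.2,
                                            iterations = 50, seed = 1L) {
  stopifnot(subsample_fraction > 0, subsample_fraction <= 1)
  if (nrow(ref_corr) != ncol(M)) stop("ref_corr dimension must match gene count")
  if (max(abs(ref_corr - t(ref_corr))) > 1e-8) stop("ref_corr must be symmetric")
  n <- nrow(M)
  n_sub <- max(1L, round(subsample_fraction * n))
  if (n_sub < 3) stop("subsample of ", n_sub, " cells is too small for correlation")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ut <- upper.tri(ref_corr)
  sim <- dist_ <- numeric(iterations)
  for (it in seq_len(iterations)) {
    idx <- sample.int(n, n_sub)
    cc <- suppressWarnings(stats::cor(M[idx, , drop = FALSE]))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 1
    sim[it] <- stats::cor(ref_corr[ut], cc[ut])
    dist_[it] <- sqrt(sum((ref_corr - cc)^2))
  }
  tibble::tibble(iteration = seq_len(iterations), similarity = sim,
                 distance = dist_)
}
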