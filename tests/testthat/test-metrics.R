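test_that("adjusted Rand index matches its degenerate cases and a pair-counting oracle", {
  a <- c(1, 1, 2, 2, 3)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(rep(1, 5), a), 0)
  expect_equal(adjusted_rand_index(c(1, 1, 2), c(1, 2, 2)),
               ari_oracle(c(1, 1, 2), c(1, 2, 2)))
  set.seed(3)
  for (i in 1:10) {
    x <- sample(1:3, 12, replace = TRUE)
    y <- sample(1:4, 12, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y), ari_oracle(x, y), tolerance = 1e-12)
  }
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("ARI agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(5)
  for (i in 1:5) {
    x <- sample(1:4, 30, replace = TRUE)
    y <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
  }
})

test_that("Hungarian accuracy equals the exhaustive-permutation optimum", {
  truth <- c("a", "a", "b", "b", "c", "c")
  pred_perm <- c(2, 2, 3, 3, 1, 1)          # truth with relabeled clusters
  expect_equal(clustering_accuracy(truth, pred_perm), 1)
  expect_equal(clustering_accuracy(rep(c("a", "b", "c"), 4), rep(1, 12)), 1 / 3)
  set.seed(11)
  for (i in 1:20) {
    t <- sample(1:5, 14, replace = TRUE)
    p <- sample(1:4, 14, replace = TRUE)
    expect_equal(clustering_accuracy(t, p), acc_oracle(t, p))
  }
})

test_that("partition metrics are invariant to relabeling", {
  set.seed(2)
  t <- sample(1:3, 20, replace = TRUE)
  p <- sample(1:3, 20, replace = TRUE)
  relab <- c(7, 5, 9)[p]
  expect_equal(adjusted_rand_index(t, p), adjusted_rand_index(t, relab))
  expect_equal(clustering_accuracy(t, p), clustering_accuracy(t, relab))
  # Hungarian matching dominates any fixed identity mapping
  expect_gte(clustering_accuracy(t, p), mean(t == p))
})

test_that("macro F1 follows the per-class confusion arithmetic", {
  truth <- c("x", "x", "x", "y", "y", "y")
  expect_equal(macro_f1(truth, truth, mapping = "identity"), 1)
  # class x: TP = 2, FP = 1, FN = 1 -> F1 = 2/3; class y symmetric
  pred <- c("x", "x", "y", "x", "y", "y")
  expect_equal(macro_f1(truth, pred, mapping = "identity"), 2 / 3)
  # a never-predicted class contributes 0
  # class x: TP = 3, FP = 3, FN = 0 -> F1 = 2/3; class y never predicted -> 0
  pred2 <- c("x", "x", "x", "x", "x", "x")
  expect_equal(macro_f1(truth, pred2, mapping = "identity"), 1 / 3)
  # hungarian mapping recovers a cluster-id permutation
  expect_equal(macro_f1(truth, c(9, 9, 9, 4, 4, 4)), 1)
})

test_that("macro one-vs-rest AUC matches rank arithmetic and its symmetries", {
  truth <- c("a", "a", "b", "b")
  onehot <- cbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1))
  expect_equal(macro_auc_ovr(truth, onehot), 1)
  expect_equal(macro_auc_ovr(truth, cbind(a = rep(0.3, 4), b = rep(0.3, 4))), 0.5)
  set.seed(4)
  scores <- cbind(a = runif(10), b = runif(10))
  truth10 <- sample(c("a", "b"), 10, replace = TRUE)
  expect_equal(macro_auc_ovr(truth10, -scores),
               1 - macro_auc_ovr(truth10, scores))
  # invariance under strictly monotone transforms
  expect_equal(macro_auc_ovr(truth10, exp(3 * scores)),
               macro_auc_ovr(truth10, scores))
})

test_that("per-class AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  truth <- sample(c("a", "b"), 40, replace = TRUE)
  sc <- runif(40)
  ours <- macro_auc_ovr(truth, cbind(a = sc, b = -sc))
  ref_a <- as.numeric(pROC::auc(pROC::roc(truth == "a", sc, quiet = TRUE,
                                          direction = "<")))
  ref_b <- as.numeric(pROC::auc(pROC::roc(truth == "b", -sc, quiet = TRUE,
                                          direction = "<")))
  expect_equal(ours, mean(c(ref_a, ref_b)), tolerance = 1e-12)
})

test_that("silhouette matches hand values, bounds, and a brute-force oracle", {
  x <- matrix(c(0, 1, 10, 11), 4, 1)
  labs <- c("u", "u", "v", "v")
  # point 0: a = 1, b = 10.5
  expect_equal(silhouette_mean(x, labs),
               mean(c(9.5 / 10.5, 8.5 / 9.5, 8.5 / 9.5, 9.5 / 10.5)))
  # two co-located clusters: a = b on average -> mean s <= 0
  y <- matrix(c(0, 1, 0, 1), 4, 1)
  expect_lte(silhouette_mean(y, c("p", "p", "q", "q")), 0)
  set.seed(9)
  for (i in 1:5) {
    M <- matrix(rnorm(30 * 3), 30, 3)
    labs30 <- sample(1:4, 30, replace = TRUE)
    val <- silhouette_mean(M, labs30)
    expect_equal(val, silhouette_oracle(M, labs30), tolerance = 1e-9)
    expect_true(val >= -1 && val <= 1)
  }
  expect_error(silhouette_mean(x, rep("u", 4)), "2 clusters")
})

test_that("silhouette agrees with the cluster package", {
  skip_if_not_installed("cluster")
  set.seed(10)
  M <- matrix(rnorm(25 * 4), 25, 4)
  labs <- sample(1:3, 25, replace = TRUE)
  ref <- mean(cluster::silhouette(labs, dist(M))[, "sil_width"])
  expect_equal(silhouette_mean(M, labs), ref, tolerance = 1e-9)
})

test_that("CBDir scores aligned, opposed, and mixed velocities as expected", {
  coords <- rbind(c(0, 0), c(1, 0), c(0, 1))
  labs <- c("src", "tgt", "tgt")
  nb <- list(2L, 1L, 1L)                      # cell 1 borders cell 2 only
  v_par <- rbind(c(1, 0), c(0, 0), c(0, 0))
  expect_equal(cbdir(coords, v_par, nb, labs, "src", "tgt"), 1)
  v_anti <- rbind(c(-1, 0), c(0, 0), c(0, 0))
  expect_equal(cbdir(coords, v_anti, nb, labs, "src", "tgt"), -1)
  nb2 <- list(c(2L, 3L), 1L, 1L)              # one parallel, one orthogonal
  expect_equal(cbdir(coords, v_par, nb2, labs, "src", "tgt"), 0.5)
  # no boundary cells -> missing, not zero
  nb3 <- list(integer(0), 1L, 1L)
  expect_true(is.na(cbdir(coords, v_par, nb3, labs, "src", "tgt")))
})

test_that("CBDir is invariant under joint rigid rotation", {
  set.seed(12)
  coords <- matrix(rnorm(20), 10, 2)
  vel <- matrix(rnorm(20), 10, 2)
  labs <- rep(c("s", "t"), each = 5)
  nb <- lapply(1:10, function(i) setdiff(sample(1:10, 4), i))
  base <- cbdir(coords, vel, nb, labs, "s", "t")
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(cbdir(coords %*% R, vel %*% R, nb, labs, "s", "t"), base,
               tolerance = 1e-12)
})

test_that("gene-level Pearson handles identity, affine maps, and constant genes", {
  X <- toy_counts(6, 4)
  tab <- gene_pearson(X, X)
  expect_equal(tab$r[!is.na(tab$r)], rep(1, sum(!is.na(tab$r))),
               tolerance = 1e-12)
  aff <- sweep(sweep(X, 2, c(2, 3, 1, 5), "*"), 2, c(1, 0, 2, 7), "+")
  expect_equal(gene_pearson(X, aff)$r, rep(1, 4), tolerance = 1e-12)
  Xc <- X; Xc[, 2] <- 3                     # constant gene in raw
  tab2 <- gene_pearson(Xc, Xc + matrix(runif(24), 6, 4))
  expect_true(is.na(tab2$r[2]))
  sm <- gene_pearson_summary(tab2)
  expect_identical(sm$n_excluded, 1L)
  expect_identical(sm$n_defined, 3L)
})

test_that("leakage ratio is the wrong-over-correct marker mean", {
  M <- matrix(c(4, 4, 1, 1,
                4, 4, 1, 1,
                2, 2, 2, 2), 4, 3,
              dimnames = list(paste0("c", 1:4), paste0("g", 1:3)))
  expect_equal(leakage_ratio(M, "g1", c("c1", "c2"), c("c3", "c4")), 0.25)
  expect_equal(leakage_ratio(M, "g3", c("c1", "c2"), c("c3", "c4")), 1)
  M0 <- M; M0[c("c3", "c4"), "g1"] <- 0
  expect_equal(leakage_ratio(M0, "g1", c("c1", "c2"), c("c3", "c4")), 0)
  expect_error(leakage_ratio(M, "g1", c("c1"), c("c1", "c2")), "disjoint")
  Mz <- M; Mz[c("c1", "c2"), "g1"] <- 0
  expect_error(leakage_ratio(Mz, "g1", c("c1", "c2"), c("c3", "c4")), "zero")
})

test_that("correlation-structure agreement is exact at full sampling and seeded", {
  set.seed(20)
  M <- matrix(rnorm(40 * 5), 40, 5)
  M[, 5] <- M[, 4]                           # two identical genes
  ref <- suppressWarnings(stats::cor(M))
  full <- correlation_structure_agreement(ref, M, subsample_fraction = 1,
                                          iterations = 3, seed = 1)
  expect_equal(full$similarity, rep(1, 3), tolerance = 1e-12)
  expect_equal(full$distance, rep(0, 3), tolerance = 1e-12)

  r1 <- correlation_structure_agreement(ref, M, 0.2, iterations = 50, seed = 7)
  r2 <- correlation_structure_agreement(ref, M, 0.2, iterations = 50, seed = 7)
  expect_identical(r1, r2)
  expect_identical(nrow(r1), 50L)
  expect_error(correlation_structure_agreement(ref, M[1:8, ], 0.2, 5, 1),
               "too small")
})

test_that("the evaluation table reports every metric with a status", {
  sim <- simulate_counts(simulation_config(n_cells = 40, n_genes = 20, seed = 2))
  tab <- evaluate_imputation(sim$X, sim$X, truth = sim$labels$label,
                             pred = sim$labels$label)
  expect_setequal(tab$metric,
                  c("gene_pearson_mean", "ari", "clustering_accuracy",
                    "macro_f1", "silhouette_mean", "macro_auc_ovr", "cbdir"))
  expect_equal(tab$value[tab$metric == "gene_pearson_mean"], 1)
  expect_equal(tab$value[tab$metric == "ari"], 1)
  expect_identical(tab$status[tab$metric == "cbdir"], "skipped")
})
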