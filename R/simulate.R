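#' Simulation configuration
#'
#' Defines a clustered Gamma-Poisson (negative binomial) expression model
#' with per-entry Bernoulli dropout — the data-generating picture the
#' imputer assumes: transcriptional bursting gives overdispersed counts, and
#' capture failure zeroes out entries at random on top of them.
#'
#' Each cell type receives a gene expression profile built from shared
#' log-normal base means plus an exclusive block of marker genes up-regulated
#' by `marker_fold`, so marker leakage and recovery have unambiguous ground
#' truth. Per-cell depth factors are log-normal. Dropout is either a constant
#' Bernoulli rate or (default) logistic-decreasing in log mean expression,
#' centered at the median true mean — lowly expressed entries drop out more
#' often, which is what makes technical zeros statistically distinguishable
#' from biological ones.
#'
#' @param n_cells,n_genes,k_types Problem sizes (defaults 300 cells, 150
#'   genes, 3 types).
#' @param type_proportions Type mixing weights (default uniform); must sum
#'   to 1.
#' @param theta_true Shared NB dispersion (default 2, strongly
#'   overdispersed).
#' @param dropout_mode `"logistic"` (mean-dependent) or `"constant"`.
#' @param dropout_rate Constant-mode Bernoulli rate, and the logistic-mode
#'   rate at the median log mean (default 0.5).
#' @param dropout_slope Logistic steepness per unit log mean (default 1).
#' @param base_meanlog,base_sdlog Log-normal base gene means (defaults
#'   log(2), 0.6).
#' @param marker_fold Fold change of each type's exclusive marker block
#'   (default 3, a subtle-subtype regime in which dropout visibly degrades
#'   cluster separability).
#' @param markers_per_type Number of exclusive marker genes per type
#'   (default `n_genes %/% (5 * k_types)`, at least 3).
#' @param depth_sdlog Log-normal sigma of per-cell depth factors
#'   (default 0.3).
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   configuration.
#' @return A list of class `scprior_simconfig`.
#' @export
simulation_config <- function(n_cells = 300, n_genes = 150, k_types = 3,
                              type_proportions = NULL, theta_true = 2,
                              dropout_mode = c("logistic", "constant"),
                              dropout_rate = 0.5, dropout_slope = 1,
                              base_meanlog = log(2), base_sdlog = 0.6,
                              marker_fold = 3, markers_per_type = NULL,
                              depth_sdlog = 0.3, seed = 1L) {
  dropout_mode <- match.arg(dropout_mode)
  if (is.null(type_proportions)) type_proportions <- rep(1 / k_types, k_types)
  stopifnot(length(type_proportions) == k_types,
            abs(sum(type_proportions) - 1) < 1e-8,
            all(type_proportions > 0),
            theta_true > 0, dropout_rate >= 0, dropout_rate < 1)
  if (is.null(markers_per_type)) {
    markers_per_type <- max(3L, n_genes %/% (5L * k_types))
  }
  if (markers_per_type * k_types > n_genes) stop("too many marker genes for n_genes")
  structure(list(n_cells = n_cells, n_genes = n_genes, k_types = k_types,
                 type_proportions = type_proportions, theta_true = theta_true,
                 dropout_mode = dropout_mode, dropout_rate = dropout_rate,
                 dropout_slope = dropout_slope, base_meanlog = base_meanlog,
                 base_sdlog = base_sdlog, marker_fold = marker_fold,
                 markers_per_type = markers_per_type,
                 depth_sdlog = depth_sdlog, seed = as.integer(seed)),
            class = "scprior_simconfig")
}

#' Simulate a clustered count matrix with dropout
#'
#' Draws type assignments multinomially, per-cell depth factors log-normally,
#' sets the true mean `mu_true[i, j] = depth_i * profile[type_i, j]`, draws
#' complete counts from NB(mean = mu_true, dispersion = theta_true) — the
#' Gamma-Poisson mixture — and finally zeroes entries by independent
#' Bernoulli dropout. Fully determined by the seed in the configuration.
#'
#' @param cfg A [simulation_config()].
#' @return List of class `scprior_sim`: `X` (post-dropout counts, validated),
#'   `X_complete` (pre-dropout), `mu_true`, `labels` (tibble as from
#'   [read_labels()]), `dropout_mask` (TRUE where an entry was zeroed by
#'   dropout), `dropout_prob`, `profiles` (k x m), `depth`, `markers`
#'   (list of marker gene ids per type), `config`.
#' @export
simulate_counts <- function(cfg = simulation_config()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  n <- cfg$n_cells; m <- cfg$n_genes; k <- cfg$k_types

  cell_ids <- sprintf("cell%0*d", nchar(n), seq_len(n))
  gene_ids <- sprintf("gene%0*d", nchar(m), seq_len(m))
  type_names <- paste0("type", seq_len(k))

  base <- stats::rlnorm(m, cfg$base_meanlog, cfg$base_sdlog)
  profiles <- matrix(rep(base, each = k), k, m,
                     dimnames = list(type_names, gene_ids))
  markers <- vector("list", k)
  names(markers) <- type_names
  for (l in seq_len(k)) {
    idx <- ((l - 1) * cfg$markers_per_type + 1):(l * cfg$markers_per_type)
    profiles[l, idx] <- profiles[l, idx] * cfg$marker_fold
    markers[[l]] <- gene_ids[idx]
  }

  type_of <- sample.int(k, n, replace = TRUE, prob = cfg$type_proportions)
  if (length(unique(type_of)) < k) stop("degenerate simulation: empty type; increase n_cells")
  depth <- stats::rlnorm(n, 0, cfg$depth_sdlog)
  mu_true <- depth * profiles[type_of, , drop = FALSE]
  dimnames(mu_true) <- list(cell_ids, gene_ids)

  X_complete <- matrix(stats::rnbinom(n * m, mu = mu_true, size = cfg$theta_true),
                       n, m, dimnames = dimnames(mu_true))

  if (cfg$dropout_mode == "constant") {
    dropout_prob <- matrix(cfg$dropout_rate, n, m)
  } else {
    mid <- stats::median(log(mu_true))
    dropout_prob <- stats::plogis(stats::qlogis(cfg$dropout_rate) +
                                    cfg$dropout_slope * (mid - log(mu_true)))
  }
  dimnames(dropout_prob) <- dimnames(mu_true)
  drop_draw <- matrix(stats::runif(n * m) < dropout_prob, n, m)
  dropout_mask <- drop_draw & X_complete > 0   # only entries actually zeroed
  X <- X_complete
  X[drop_draw] <- 0

  # a cell losing everything to dropout cannot be processed downstream
  dead <- rowSums(X) == 0
  if (any(dead)) {
    for (i in which(dead)) {
      j <- which.max(X_complete[i, ])
      X[i, j] <- X_complete[i, j]
      dropout_mask[i, j] <- FALSE
    }
  }
  dimnames(X) <- dimnames(mu_true)

  labels <- labels_from_vector(
    stats::setNames(type_names[type_of], cell_ids),
    X)

  structure(list(X = validate_counts(X), X_complete = X_complete,
                 mu_true = mu_true, labels = labels,
                 dropout_mask = dropout_mask, dropout_prob = dropout_prob,
                 profiles = profiles, depth = depth, markers = markers,
                 type_of = type_of, config = cfg),
            class = "scprior_sim")
}

#' Retain a fraction of labels (label-availability protocol)
#'
#' Keeps `round(fraction * n_labeled)` labels chosen uniformly without
#' replacement, stratified by type when every stratum can keep at least one
#' cell; the rest become unlabeled. Deterministic in the seed.
#'
#' @param labels Label tibble.
#' @param fraction Fraction in [0, 1] of labeled cells to retain.
#' @param seed Integer seed.
#' @return A label tibble with the retained subset labeled.
#' @export
subsample_labels <- function(labels, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  labeled_idx <- which(!is.na(labels$label))
  n_keep <- round(fraction * length(labeled_idx))
  out <- labels
  if (n_keep == 0) {
    out$label <- NA_character_
    return(out)
  }
  types <- unique(labels$label[labeled_idx])
  strata <- split(labeled_idx, labels$label[labeled_idx])
  keep <- integer(0)
  if (length(strata) <= n_keep && all(lengths(strata) >= 1)) {
    # proportional allocation, at least one per stratum
    alloc <- round(lengths(strata) / length(labeled_idx) * n_keep)
    alloc <- pmax(alloc, 1)
    # trim/grow to hit the exact total
    while (sum(alloc) > n_keep) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1
    while (sum(alloc) < n_keep) {
      room <- lengths(strata) - alloc
      alloc[which.max(room)] <- alloc[which.max(room)] + 1
    }
    for (l in names(strata)) {
      keep <- c(keep, sample(strata[[l]], alloc[[l]]))
    }
  } else {
    keep <- sample(labeled_idx, n_keep)
  }
  dropped <- setdiff(labeled_idx, keep)
  out$label[dropped] <- NA_character_
  attr(out, "types") <- attr(labels, "types")
  out
}

#' Inject label noise (label-corruption protocol)
#'
#' Selects `round(noise * n_labeled)` labeled cells uniformly and reassigns
#' each to a uniformly random *different* type; no fixed points by
#' construction. Deterministic in the seed.
#'
#' @param labels Label tibble with at least 2 types.
#' @param noise Corruption fraction in [0, 1].
#' @param seed Integer seed.
#' @return A label tibble with exactly `round(noise * n_labeled)` changed
#'   assignments.
#' @export
perturb_labels <- function(labels, noise, seed = 1L) {
  stopifnot(noise >= 0, noise <= 1)
  types <- attr(labels, "types")
  if (is.null(types)) types <- unique(labels$label[!is.na(labels$label)])
  if (length(types) < 2 && noise > 0) stop("label noise requires at least 2 types")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  labeled_idx <- which(!is.na(labels$label))
  n_flip <- round(noise * length(labeled_idx))
  out <- labels
  if (n_flip == 0) return(out)
  flip <- sample(labeled_idx, n_flip)
  for (i in flip) {
    others <- setdiff(types, out$label[i])
    out$label[i] <- others[sample.int(length(others), 1)]
  }
  attr(out, "types") <- types
  out
}
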