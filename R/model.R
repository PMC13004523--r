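#' Per-cell size factors
#'
#' The size factor of cell i is its total count divided by the median total
#' count over all cells. It captures library-size and capture-rate variation
#' at the observation layer: under Poisson thinning, per-molecule capture with
#' cell-specific probability p_i rescales Poisson means multiplicatively, so
#' depth is removed from the biological mean by a single per-cell factor.
#'
#' @param counts Validated cells-by-genes count matrix.
#' @return Named numeric vector `s` with one positive entry per cell; when
#'   the number of cells is odd, `median(s)` is exactly 1.
#' @export
compute_size_factors <- function(counts) {
  totals <- rowSums(counts)
  med <- stats::median(totals)
  if (med <= 0) stop("internal error: non-positive median row sum")
  stats::setNames(totals / med, rownames(counts))
}

#' Label-derived prior encoding
#'
#' Builds the two prior structures consumed by the supervised forward pass:
#' a row-stochastic membership matrix `P` (labeled cells one-hot on their
#' type's module; unlabeled rows are zero and flagged in `labeled`) and a
#' prototype profile matrix `H_prior` whose row for type l is the arithmetic
#' mean of the raw count rows of cells labeled l. Types with no labeled cell,
#' and "anonymous" modules beyond the number of types when `k > C`, receive
#' the global mean row so the prototype stays on the raw-count scale.
#'
#' @param labels Label tibble from [read_labels()]/[labels_from_vector()].
#' @param counts Validated count matrix.
#' @param k Number of latent modules; must be at least the number of
#'   distinct labels.
#' @return List with `P` (n x k), `H_prior` (k x m), `labeled` (logical per
#'   cell), `types` (module-to-type names, `NA` for anonymous modules).
#' @export
build_prior_encoding <- function(labels, counts, k) {
  stopifnot(identical(labels$cell, rownames(counts)))
  types <- attr(labels, "types")
  if (is.null(types)) types <- unique(labels$label[!is.na(labels$label)])
  types <- types[types %in% labels$label]
  C <- length(types)
  if (k < C) stop("k (", k, ") must be >= number of labeled types (", C, ")")
  n <- nrow(counts); m <- ncol(counts)
  P <- matrix(0, n, k, dimnames = list(rownames(counts), NULL))
  labeled <- !is.na(labels$label)
  if (C > 0) {
    col <- match(labels$label, types)
    P[cbind(which(labeled), col[labeled])] <- 1
  }
  global_mean <- colMeans(counts)
  H_prior <- matrix(rep(global_mean, each = k), k, m,
                    dimnames = list(NULL, colnames(counts)))
  for (l in seq_len(C)) {
    members <- labeled & labels$label == types[l]
    if (any(members)) {
      H_prior[l, ] <- colMeans(counts[members, , drop = FALSE])
    }
  }
  module_names <- c(types, rep(NA_character_, k - C))
  list(P = P, H_prior = H_prior, labeled = labeled, types = module_names)
}

#' Moment estimate of per-gene batch correction factors
#'
#' Multiplicative per-(gene, batch) factors kappa on the observation layer.
#' They are estimated once from depth-normalized data (batch mean of
#' X_ij / s_i per gene, on the log1p scale) and centered per gene across
#' batches on the log scale so that the geometric mean of kappa over batches
#' is 1 for every gene — the identifiability constraint that keeps batch
#' effects from absorbing biological mean expression.
#'
#' @param counts Validated count matrix.
#' @param batches Batch tibble from [read_batches()].
#' @param s Size factors from [compute_size_factors()].
#' @return List with `log_kappa` (genes x batches, rows mean-zero),
#'   `batch_of` (integer batch index per cell), `batches` (batch names).
#' @export
estimate_batch_correction <- function(counts, batches, s) {
  stopifnot(identical(batches$cell, rownames(counts)))
  batch_names <- attr(batches, "batches")
  if (is.null(batch_names)) batch_names <- unique(batches$batch)
  b <- match(batches$batch, batch_names)
  norm <- counts / s
  log_kappa <- matrix(0, ncol(counts), length(batch_names),
                      dimnames = list(colnames(counts), batch_names))
  for (j in seq_along(batch_names)) {
    sub <- norm[b == j, , drop = FALSE]
    log_kappa[, j] <- log1p(colMeans(sub))
  }
  log_kappa <- log_kappa - rowMeans(log_kappa)
  list(log_kappa = log_kappa, batch_of = b, batches = batch_names)
}

#' Initialize trainable parameters
#'
#' W and H start as independent uniform(0, 0.1) draws: a small strictly
#' positive start keeps the ReLU active everywhere so early gradients flow.
#' Dropout logits start at 0 (pi = 0.5), the raw dispersion at 0
#' (theta = softplus(0) + 1e-4), and the linear probe at zero. All draws are
#' governed by `seed`, so a fit is reproducible bit for bit.
#'
#' @param n,m Number of cells and genes.
#' @param k Number of latent modules.
#' @param C Number of label classes (0 disables the probe).
#' @param seed Integer RNG seed.
#' @return List of parameter arrays: `W`, `H`, `rho`, `theta_raw`,
#'   `probe_w`, `probe_b`.
#' @export
init_params <- function(n, m, k, C = 0L, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  list(
    W = matrix(stats::runif(n * k, 0, 0.1), n, k),
    H = matrix(stats::runif(k * m, 0, 0.1), k, m),
    rho = numeric(m),
    theta_raw = 0,
    probe_w = if (C > 0) matrix(0, k, C) else NULL,
    probe_b = if (C > 0) numeric(C) else NULL
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

row_softmax <- function(M) {
  e <- exp(M - apply(M, 1, max))
  e / rowSums(e)
}

#' Forward pass of the factorization model
#'
#' Maps unconstrained parameters to the model quantities. Nonnegativity comes
#' from ReLU; the cell factor is made row-stochastic by a row-wise softmax.
#' With a prior, labeled cells are shrunk halfway toward their one-hot
#' membership row, and the gene factor halfway toward the prototype profiles:
#' \deqn{W^+_i = (P_i + softmax(ReLU(W))_i)/2} for labeled cells (softmax row
#' alone for unlabeled ones), \deqn{H^+ = (H_{prior} + ReLU(H))/2.} Without a
#' prior, \eqn{W^+ = softmax(ReLU(W))} and \eqn{H^+ = ReLU(H)}. The
#' biological mean is \eqn{\mu = W^+ H^+}; the observation-scale mean
#' multiplies in the size factor and, when present, the batch factor:
#' \eqn{\mu^{adj}_{ij} = s_i \kappa_{j,b(i)} \mu_{ij}}. Observation noise is
#' not sampled — the reconstruction is the conditional mean, and
#' stochasticity is carried by the ZINB likelihood. Dropout probabilities are
#' one free logit per gene, broadcast over cells.
#'
#' @param params Parameter list from [init_params()].
#' @param s Size factor vector.
#' @param prior Optional prior encoding from [build_prior_encoding()].
#' @param batch Optional batch correction from [estimate_batch_correction()].
#' @return List with `W_plus`, `H_plus`, `mu`, `mu_adjusted`, `pi`, `theta`,
#'   plus cached intermediates used by the backward pass.
#' @export
model_forward <- function(params, s, prior = NULL, batch = NULL) {
  if (any(!vapply(params[c("W", "H", "rho", "theta_raw")],
                  function(p) all(is.finite(p)), logical(1)))) {
    stop("non-finite model parameter in forward pass")
  }
  W_hat <- pmax(params$W, 0)
  H_hat <- pmax(params$H, 0)
  S <- row_softmax(W_hat)
  n <- nrow(S); k <- ncol(S)
  if (!is.null(prior)) {
    W_plus <- S
    lab <- prior$labeled
    if (any(lab)) {
      W_plus[lab, ] <- 0.5 * (prior$P[lab, , drop = FALSE] + S[lab, , drop = FALSE])
    }
    H_plus <- 0.5 * (prior$H_prior + H_hat)
  } else {
    W_plus <- S
    H_plus <- H_hat
  }
  mu <- W_plus %*% H_plus
  sk <- matrix(s, n, ncol(mu))
  if (!is.null(batch)) {
    kappa <- exp(batch$log_kappa)          # genes x batches
    sk <- sk * t(kappa[, batch$batch_of, drop = FALSE])
  }
  mu_adjusted <- sk * mu
  theta <- softplus(params$theta_raw) + 1e-4
  pi_gene <- stats::plogis(params$rho)
  list(W_plus = W_plus, H_plus = H_plus, mu = mu, mu_adjusted = mu_adjusted,
       pi = pi_gene, theta = theta,
       S = S, sk = sk)
}
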