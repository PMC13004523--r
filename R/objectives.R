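#' Loss switches
#'
#' The four loss terms are combined with binary switches: each lambda is
#' exactly 0 (term off) or 1 (term on). Fractional weights are rejected.
#'
#' @param nmf,zinb,zscore,class_ Each 0 or 1.
#' @return Named list of the four switches.
#' @export
loss_weights <- function(nmf = 1, zinb = 1, zscore = 1, class_ = 1) {
  w <- list(nmf = nmf, zinb = zinb, zscore = zscore, class_ = class_)
  for (nm in names(w)) {
    if (!w[[nm]] %in% c(0, 1)) stop("lambda_", nm, " must be 0 or 1")
  }
  w
}

#' Mean-Frobenius reconstruction loss
#'
#' `||X - mu_adjusted||_F / (n * m)`: the Frobenius norm itself (not its
#' square) divided by the entry count.
#'
#' @param X Observed count matrix.
#' @param mu_adjusted Observation-scale reconstruction of the same shape.
#' @return Scalar loss.
#' @export
nmf_loss <- function(X, mu_adjusted) {
  if (!all(dim(X) == dim(mu_adjusted))) stop("shape mismatch in nmf_loss")
  sqrt(sum((X - mu_adjusted)^2)) / length(X)
}

#' Zero-inflated negative binomial log-PMF
#'
#' Mixture of a point mass at zero (weight `pi`) and a negative binomial
#' with mean `mu` and dispersion `theta` (variance mu + mu^2/theta):
#' \deqn{P(0) = \pi + (1-\pi)\left(\frac{\theta}{\mu+\theta}\right)^\theta}
#' \deqn{P(x) = (1-\pi)\frac{\Gamma(x+\theta)}{\Gamma(\theta)\,\Gamma(x+1)}
#'   \left(\frac{\mu}{\mu+\theta}\right)^x
#'   \left(\frac{\theta}{\mu+\theta}\right)^\theta, \quad x > 0.}
#' Computed in log space: log-gamma functions for the x > 0 branch and a
#' log-sum-exp for the zero branch. Vectorized over all arguments.
#'
#' @param x Nonnegative integer count(s).
#' @param mu Positive mean(s).
#' @param theta Positive dispersion.
#' @param pi Structural-zero probability in [0, 1); `pi = 1` is permitted
#'   only with `x = 0` (log-probability 0); with `x > 0` it yields `-Inf`.
#' @return Log-probability, same length as the broadcast arguments.
#' @export
zinb_log_pmf <- function(x, mu, theta, pi) {
  nb0 <- theta * (log(theta) - log(mu + theta))     # log NB(0)
  log_pi <- log(pi)
  log_1mpi <- log1p(-pi)
  # x == 0: logsumexp(log pi, log(1-pi) + nb0)
  a <- pmax(log_pi, log_1mpi + nb0)
  zero_branch <- ifelse(pi == 1, 0,
                        ifelse(pi == 0, nb0,
                               a + log(exp(log_pi - a) + exp(log_1mpi + nb0 - a))))
  pos_branch <- log_1mpi + lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    x * (log(mu) - log(mu + theta)) + nb0
  ifelse(x == 0, zero_branch, pos_branch)
}

#' Mean ZINB negative log-likelihood
#'
#' Average of `-zinb_log_pmf` over all n * m entries, with the observation
#' mean taken as `mu_adjusted` clipped below at 1e-8 (the PMF is undefined at
#' mu = 0, which the ReLU factors can produce; the clip is inert for well-fit
#' entries). The per-gene dropout probability is broadcast over cells.
#'
#' @param X Observed counts.
#' @param out Forward output from [model_forward()].
#' @return Scalar mean negative log-likelihood.
#' @export
zinb_nll <- function(X, out) {
  if (!all(dim(X) == dim(out$mu_adjusted))) stop("shape mismatch in zinb_nll")
  m_clip <- pmax(out$mu_adjusted, 1e-8)
  pi_mat <- matrix(out$pi, nrow(X), ncol(X), byrow = TRUE)
  lp <- zinb_log_pmf(X, m_clip, out$theta, pi_mat)
  if (any(!is.finite(lp))) {
    bad <- which(!is.finite(lp), arr.ind = TRUE)[1, ]
    stop("non-finite ZINB log-likelihood at entry (", bad[1], ",", bad[2], ")")
  }
  -mean(lp)
}

#' Row-wise z-scores with the population standard deviation
#'
#' Each row is centered by its mean and divided by its population standard
#' deviation (divisor m, not m - 1) plus epsilon = 1e-8; constant rows map
#' to (numerically) zero vectors.
#'
#' @param M Numeric matrix with at least 2 columns.
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(M) {
  if (ncol(M) < 2) stop("zscore_rows requires at least 2 columns")
  ctr <- M - rowMeans(M)
  sd_pop <- sqrt(rowMeans(ctr^2))
  ctr / (sd_pop + 1e-8)
}

#' Z-score consistency loss
#'
#' Mean squared difference between the row-wise z-scores of the observed
#' matrix and of the reconstruction, over all n * m entries. Because
#' z-scoring removes per-row scale and offset, any per-cell rescaling of the
#' reconstruction (in particular the size factors) leaves the loss unchanged;
#' what is penalized is distortion of each cell's relative expression shape.
#'
#' @param X Observed counts.
#' @param mu Reconstruction (biological or depth-adjusted scale; identical
#'   result by row-scale invariance).
#' @return Scalar loss.
#' @export
zscore_loss <- function(X, mu) {
  if (!all(dim(X) == dim(mu))) stop("shape mismatch in zscore_loss")
  mean((zscore_rows(X) - zscore_rows(mu))^2)
}

#' Linear-probe classification loss
#'
#' Cross-entropy of a linear softmax probe read off the prior-aligned cell
#' embedding: logits `W_plus %*% probe_w + probe_b`, averaged over labeled
#' cells only. Enforces that cell identity is linearly decodable from the
#' latent embedding.
#'
#' @param W_plus Row-stochastic cell factor (n x k).
#' @param y Integer class index per cell (NA for unlabeled).
#' @param probe_w k x C probe weights.
#' @param probe_b Length-C probe bias.
#' @return Scalar mean cross-entropy over labeled cells.
#' @export
classification_loss <- function(W_plus, y, probe_w, probe_b) {
  lab <- which(!is.na(y))
  if (length(lab) == 0) stop("classification loss requires at least one labeled cell")
  logits <- W_plus[lab, , drop = FALSE] %*% probe_w +
    matrix(probe_b, length(lab), length(probe_b), byrow = TRUE)
  logp <- logits - apply(logits, 1, max)
  logp <- logp - log(rowSums(exp(logp)))
  -mean(logp[cbind(seq_along(lab), y[lab])])
}

#' Switched total objective
#'
#' Computes each enabled term once and returns the breakdown together with
#' the lambda-weighted total. Terms with lambda = 0 are reported as 0 and
#' flagged disabled.
#'
#' @param X Observed counts.
#' @param out Forward output.
#' @param weights Switch list from [loss_weights()].
#' @param y Integer class labels (required when the classification switch
#'   is on).
#' @param params Parameter list (for the probe).
#' @return List `nmf`, `zinb`, `zscore`, `class_`, `total`, `disabled`.
#' @export
total_loss <- function(X, out, weights, y = NULL, params = NULL) {
  terms <- list(nmf = 0, zinb = 0, zscore = 0, class_ = 0)
  if (weights$nmf == 1) terms$nmf <- nmf_loss(X, out$mu_adjusted)
  if (weights$zinb == 1) terms$zinb <- zinb_nll(X, out)
  if (weights$zscore == 1) terms$zscore <- zscore_loss(X, out$mu)
  if (weights$class_ == 1) {
    if (is.null(y) || all(is.na(y))) {
      stop("lambda_class = 1 requires labeled cells")
    }
    terms$class_ <- classification_loss(out$W_plus, y, params$probe_w, params$probe_b)
  }
  total <- weights$nmf * terms$nmf + weights$zinb * terms$zinb +
    weights$zscore * terms$zscore + weights$class_ * terms$class_
  c(terms, list(total = total,
                disabled = names(weights)[unlist(weights) == 0]))
}
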