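# Shared fixtures. Heavy fits (the 300x150 recovery family) are computed
# once per test session and cached here.

.fixture_cache <- new.env(parent = emptyenv())

toy_counts <- function(n = 5, m = 4, seed = 42, with_zeros = TRUE) {
  set.seed(seed)
  X <- matrix(rpois(n * m, 3) + 1, n, m,
              dimnames = list(paste0("c", seq_len(n)), paste0("g", seq_len(m))))
  if (with_zeros) X[cbind(seq_len(min(n, m)), seq_len(min(n, m)))] <- 0
  validate_counts(X)
}

toy_labels <- function(X, types = c("A", "B")) {
  n <- nrow(X)
  labels_from_vector(
    stats::setNames(rep(types, length.out = n), rownames(X)), X)
}

# small supervised instance for gradient and algebra checks
grad_instance <- function(seed = 3) {
  X <- toy_counts(5, 4, seed = 42)
  labels <- toy_labels(X)
  s <- compute_size_factors(X)
  prior <- build_prior_encoding(labels, X, k = 2)
  y <- match(labels$label, attr(labels, "types"))
  params <- init_params(5, 4, 2, C = 2, seed = seed)
  set.seed(seed)
  params$W <- params$W + 0.05          # keep ReLU away from its kink
  params$H <- params$H + 0.05
  params$rho <- rnorm(4, 0, 0.3)
  params$theta_raw <- 0.4
  params$probe_w <- matrix(rnorm(4, 0, 0.3), 2, 2)
  params$probe_b <- rnorm(2, 0, 0.1)
  list(X = X, labels = labels, s = s, prior = prior, y = y, params = params)
}

flatten_params <- function(p) {
  unlist(p[c("W", "H", "rho", "theta_raw", "probe_w", "probe_b")])
}

unflatten_params <- function(v, p) {
  i <- 0
  for (nm in c("W", "H", "rho", "theta_raw", "probe_w", "probe_b")) {
    len <- length(p[[nm]])
    p[[nm]][] <- v[i + seq_len(len)]
    i <- i + len
  }
  p
}

# numerical gradient of the total loss by central differences
numeric_gradient <- function(inst, weights, h = 1e-6) {
  v0 <- flatten_params(inst$params)
  g <- numeric(length(v0))
  for (i in seq_along(v0)) {
    vp <- v0; vp[i] <- vp[i] + h
    vm <- v0; vm[i] <- vm[i] - h
    fp <- loss_and_grad(inst$X, unflatten_params(vp, inst$params), inst$s,
                        weights, inst$prior, NULL, inst$y)$terms$total
    fm <- loss_and_grad(inst$X, unflatten_params(vm, inst$params), inst$s,
                        weights, inst$prior, NULL, inst$y)$terms$total
    g[i] <- (fp - fm) / (2 * h)
  }
  g
}

# the 300x150 study-condition fixture family, fitted with true labels,
# all switches on; cached across test files
recovery_runs <- function() {
  if (!is.null(.fixture_cache$recovery)) return(.fixture_cache$recovery)
  runs <- lapply(0:2, function(sd) {
    sim <- simulate_counts(simulation_config(seed = sd))
    fit <- fit_factor_model(sim$X, sim$labels,
                            config = training_config(seed = sd))
    imp <- impute_zeros(sim$X, fit)
    list(seed = sd, sim = sim, fit = fit, imp = imp)
  })
  .fixture_cache$recovery <- runs
  runs
}

# brute-force oracles -------------------------------------------------------

ari_oracle <- function(a, b) {
  n <- length(a)
  agree <- 0; n_pairs <- 0
  same_a <- same_b <- logical(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      n_pairs <- n_pairs + 1
      same_a <- c(same_a, a[i] == a[j])
      same_b <- c(same_b, b[i] == b[j])
    }
  }
  obs <- sum(same_a == same_b)
  # expected-index correction in pair-count form
  tab <- table(a, b)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(tab); rc <- sum_comb(rowSums(tab)); cc <- sum_comb(colSums(tab))
  exp_idx <- rc * cc / choose(n, 2)
  max_idx <- (rc + cc) / 2
  if (max_idx == exp_idx) return(0)
  (idx - exp_idx) / (max_idx - exp_idx)
}

acc_oracle <- function(truth, pred) {
  classes <- unique(truth); clusters <- unique(pred)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  k <- max(length(classes), length(clusters))
  cls <- c(classes, rep(NA, k - length(classes)))
  best <- 0
  for (p in perms(seq_len(k))) {
    mapped <- cls[p[match(pred, clusters)]]
    best <- max(best, sum(!is.na(mapped) & mapped == truth))
  }
  best / length(truth)
}

silhouette_oracle <- function(X, labels) {
  D <- as.matrix(dist(X))
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    mates <- setdiff(which(labels == own), i)
    if (length(mates) == 0) { s[i] <- 0; next }
    a <- mean(D[i, mates])
    b <- Inf
    for (cl in setdiff(unique(labels), own)) {
      b <- min(b, mean(D[i, labels == cl]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
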