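#' Training configuration
#'
#' Collects the optimizer and stopping hyper-parameters. Training uses
#' full-batch Adam with bias-corrected moments and a step-decayed learning
#' rate; it stops when the relative change of the training objective stays
#' below `eps_loss` for `patience` consecutive epochs, or at `max_epochs`.
#'
#' @param weights Loss switches from [loss_weights()].
#' @param eta0 Initial learning rate (default 0.01).
#' @param gamma Multiplicative decay factor in (0, 1) (default 0.95).
#' @param t_decay Decay interval in epochs (default 200).
#' @param eps_adam Adam denominator stabilizer (default 1e-8).
#' @param eps_loss Relative-change plateau tolerance (default 0.001).
#' @param patience Consecutive-epoch plateau window (default 10).
#' @param max_epochs Epoch cap (default 2000).
#' @param seed Integer seed controlling parameter initialization.
#' @return A list of class `scprior_config`.
#' @export
training_config <- function(weights = loss_weights(), eta0 = 0.01,
                            gamma = 0.95, t_decay = 200, eps_adam = 1e-8,
                            eps_loss = 0.001, patience = 10,
                            max_epochs = 2000, seed = 1L) {
  stopifnot(gamma > 0, gamma < 1, patience >= 1, eps_loss > 0,
            max_epochs >= 1, eta0 > 0, t_decay >= 1)
  structure(list(weights = weights, eta0 = eta0, gamma = gamma,
                 t_decay = t_decay, eps_adam = eps_adam, eps_loss = eps_loss,
                 patience = patience, max_epochs = max_epochs,
                 seed = as.integer(seed)),
            class = "scprior_config")
}

#' Learning rate at an epoch
#'
#' Step decay: `eta0 * gamma ^ floor(t / t_decay)` for 0-based epoch index t.
#'
#' @param t Epoch index (0-based).
#' @param cfg Training configuration.
#' @return The learning rate.
#' @export
lr_at <- function(t, cfg) {
  stopifnot(t >= 0)
  cfg$eta0 * cfg$gamma^floor(t / cfg$t_decay)
}

#' Plateau stopping rule
#'
#' TRUE when `|L(t) - L(t-1)| / |L(t-1)| < eps_loss` held for each of the
#' last `patience` consecutive epoch pairs. A previous loss below 1e-12 in
#' magnitude makes the ratio 0 (already converged to zero).
#'
#' @param totals Numeric vector of per-epoch totals, oldest first; needs at
#'   least `patience + 1` entries.
#' @param cfg Training configuration.
#' @return Logical.
#' @export
plateau_reached <- function(totals, cfg) {
  w <- cfg$patience
  if (length(totals) < w + 1) return(FALSE)
  recent <- utils::tail(totals, w + 1)
  prev <- recent[-length(recent)]
  curr <- recent[-1]
  rel <- ifelse(abs(prev) < 1e-12, 0, abs(curr - prev) / abs(prev))
  all(rel < cfg$eps_loss)
}

.adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) NULL else list(m = p * 0, v = p * 0)
  })
}

.adam_step <- function(params, grads, state, t, lr, eps) {
  b1 <- 0.9; b2 <- 0.999
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st <- state[[nm]]
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g^2
    mhat <- st$m / (1 - b1^t)
    vhat <- st$v / (1 - b2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

#' Fit the prior-guided factorization
#'
#' Full-batch Adam on all trainable parameters (W, H, per-gene dropout
#' logits, shared dispersion, and the linear probe when labels are used).
#' With labels present (or `mode = "prior"`), the supervised forward pass
#' shrinks labeled cells toward their one-hot membership and the gene factor
#' toward type prototypes; with `mode = "unsup"` (or no labels) the plain
#' softmax/ReLU factorization is fitted and the classification switch must
#' be off. The fit is a deterministic function of the inputs and the seed.
#'
#' @param X Validated cells-by-genes count matrix.
#' @param labels Optional label tibble ([read_labels()]); `NA` labels mark
#'   unlabeled cells.
#' @param batches Optional batch tibble ([read_batches()]).
#' @param k Number of latent modules; defaults to the number of distinct
#'   labels when labels are given.
#' @param config Training configuration from [training_config()].
#' @param mode `"auto"` (supervised iff labels carry any assignment),
#'   `"prior"`, or `"unsup"`.
#' @return An object of class `scprior_fit`: list with `params`, `output`
#'   (final forward pass), `trace` (per-epoch tibble), `stop_epoch`,
#'   `stop_reason`, `s`, `prior`, `batch`, `config`, `k`, `mode`, plus the
#'   label vector used.
#' @export
fit_factor_model <- function(X, labels = NULL, batches = NULL, k = NULL,
                             config = training_config(),
                             mode = c("auto", "prior", "unsup")) {
  mode <- match.arg(mode)
  validate_counts(X)
  has_labels <- !is.null(labels) && any(!is.na(labels$label))
  supervised <- switch(mode,
                       auto = has_labels,
                       prior = TRUE,
                       unsup = FALSE)
  if (supervised && !has_labels) stop("mode 'prior' requires labels")
  if (!supervised && config$weights$class_ == 1) {
    stop("lambda_class = 1 requires supervised mode with labels")
  }
  types <- if (has_labels) {
    tp <- attr(labels, "types")
    if (is.null(tp)) unique(labels$label[!is.na(labels$label)]) else tp[tp %in% labels$label]
  } else character(0)
  C <- length(types)
  if (is.null(k)) {
    if (C == 0) stop("k must be given when no labels are supplied")
    k <- C
  }
  if (supervised && k < C) stop("k must be >= number of label types")

  s <- compute_size_factors(X)
  prior <- if (supervised) build_prior_encoding(labels, X, k) else NULL
  batch <- if (!is.null(batches)) estimate_batch_correction(X, batches, s) else NULL
  y <- if (supervised) match(labels$label, types) else NULL

  params <- init_params(nrow(X), ncol(X), k,
                        C = if (supervised) C else 0L, seed = config$seed)
  state <- .adam_init(params)

  trace <- vector("list", config$max_epochs)
  totals <- numeric(0)
  stop_reason <- "max_epochs"
  stop_epoch <- config$max_epochs

  for (t in seq_len(config$max_epochs)) {
    lg <- loss_and_grad(X, params, s, config$weights, prior, batch, y)
    if (!is.finite(lg$terms$total)) {
      stop("non-finite total loss at epoch ", t, " (nmf=", lg$terms$nmf,
           ", zinb=", lg$terms$zinb, ", zscore=", lg$terms$zscore,
           ", class=", lg$terms$class_, ")")
    }
    lr <- lr_at(t - 1, config)
    trace[[t]] <- c(epoch = t, nmf = lg$terms$nmf, zinb = lg$terms$zinb,
                    zscore = lg$terms$zscore, class_ = lg$terms$class_,
                    total = lg$terms$total, lr = lr)
    totals <- c(totals, lg$terms$total)
    if (plateau_reached(totals, config)) {
      stop_reason <- "plateau"
      stop_epoch <- t
      break
    }
    upd <- .adam_step(params, lg$grads, state, t, lr, config$eps_adam)
    params <- upd$params
    state <- upd$state
    stop_epoch <- t
  }

  trace <- tibble::as_tibble(do.call(rbind, trace[seq_len(stop_epoch)]))
  out <- model_forward(params, s, prior, batch)
  structure(list(params = params, output = out, trace = trace,
                 stop_epoch = stop_epoch, stop_reason = stop_reason,
                 s = s, prior = prior, batch = batch, config = config,
                 k = k, mode = if (supervised) "prior" else "unsup",
                 y = y, types = types,
                 cell_ids = rownames(X), gene_ids = colnames(X)),
            class = "scprior_fit")
}

#' @export
print.scprior_fit <- function(x, ...) {
  cat("Prior-guided factorization fit (", x$mode, " mode)\n", sep = "")
  cat("  cells:", length(x$cell_ids), " genes:", length(x$gene_ids),
      " modules:", x$k, "\n")
  cat("  stopped at epoch", x$stop_epoch, "(", x$stop_reason, ")\n")
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf("  final losses: total=%.5g nmf=%.5g zinb=%.5g zscore=%.5g class=%.5g\n",
              last$total, last$nmf, last$zinb, last$zscore, last$class_))
  invisible(x)
}

#' Tidy the training trace of a fit
#'
#' One row per epoch and loss term, in long format suitable for plotting.
#'
#' @param x An `scprior_fit`.
#' @param ... Unused.
#' @return A tibble with columns `epoch`, `term`, `value`, `lr`.
#' @export
tidy.scprior_fit <- function(x, ...) {
  tr <- x$trace
  terms <- c("nmf", "zinb", "zscore", "class_", "total")
  out <- lapply(terms, function(tm) {
    tibble::tibble(epoch = tr$epoch, term = sub("_$", "", tm),
                   value = tr[[tm]], lr = tr$lr)
  })
  do.call(rbind, out)
}

#' One-row summary of a fit
#'
#' @param x An `scprior_fit`.
#' @param ... Unused.
#' @return A one-row tibble: sizes, mode, stop epoch/reason, final losses,
#'   fitted dispersion and mean dropout probability.
#' @export
glance.scprior_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  tibble::tibble(n_cells = length(x$cell_ids), n_genes = length(x$gene_ids),
                 k = x$k, mode = x$mode, stop_epoch = x$stop_epoch,
                 stop_reason = x$stop_reason, total = last$total,
                 nmf = last$nmf, zinb = last$zinb, zscore = last$zscore,
                 class_ = last$class_, theta = x$output$theta,
                 mean_dropout_prob = mean(x$output$pi))
}

#' Plot the training trace
#'
#' Loss-term trajectories over epochs on a log10 y scale.
#'
#' @param object An `scprior_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scprior_fit <- function(object, ...) {
  d <- tidy.scprior_fit(object)
  d <- d[d$value > 0 | d$term == "total", ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss", colour = "term") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
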