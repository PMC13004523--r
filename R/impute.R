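#' Zeros-only imputation
#'
#' Replaces exactly the zero entries of the observed matrix with the model's
#' observation-scale mean `mu_adjusted`; every nonzero count is preserved
#' bit for bit. Imputed values are reported on the observation scale
#' (including the size factor and any batch factor) so that imputed entries
#' are commensurate with the retained raw counts of the same cell. No
#' rounding or thresholding is applied.
#'
#' @param X Observed count matrix.
#' @param out A forward output (`model_forward()`) or an `scprior_fit`.
#' @return List of class `scprior_imputation`: `imputed` (numeric matrix),
#'   `replaced_mask` (logical matrix, TRUE exactly where `X == 0`), and
#'   `model` (the forward output used).
#' @export
impute_zeros <- function(X, out) {
  if (inherits(out, "scprior_fit")) out <- out$output
  if (!all(dim(X) == dim(out$mu_adjusted))) stop("shape mismatch in impute_zeros")
  mask <- X == 0
  imputed <- X
  imputed[mask] <- out$mu_adjusted[mask]
  structure(list(imputed = imputed, replaced_mask = mask, model = out),
            class = "scprior_imputation")
}

#' Run the full imputation pipeline from files
#'
#' load -> size factors -> label priors (if labels) -> fit -> zeros-only
#' imputation -> write the imputed matrix, the per-epoch trace CSV, and a
#' JSON run manifest (seed, configuration, stop reason, package version).
#'
#' @param counts_path Count matrix file (see [read_counts()]).
#' @param out_dir Output directory (created if missing).
#' @param labels_path,batches_path Optional label / batch TSVs.
#' @param config_path Optional YAML/JSON file of [training_config()] fields
#'   (flat keys; `lambda_nmf`, `lambda_zinb`, `lambda_zscore`,
#'   `lambda_class` set the switches).
#' @param k Number of modules; defaults to the number of label types.
#' @param seed Overrides the seed from the config file when given.
#' @param mode `"auto"`, `"prior"` or `"unsup"`.
#' @param orientation On-disk orientation of the count matrix.
#' @param dialect Output dialect for the imputed matrix.
#' @return Invisibly, a list with the fit, imputation, and output paths.
#' @export
run_pipeline <- function(counts_path, out_dir, labels_path = NULL,
                         batches_path = NULL, config_path = NULL, k = NULL,
                         seed = NULL, mode = "auto",
                         orientation = "cells-as-rows",
                         dialect = c("matrix-market", "dense")) {
  dialect <- match.arg(dialect)
  X <- read_counts(counts_path, orientation)
  labels <- if (!is.null(labels_path)) read_labels(labels_path, X) else NULL
  batches <- if (!is.null(batches_path)) read_batches(batches_path, X) else NULL
  config <- if (!is.null(config_path)) read_run_config(config_path) else training_config()
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(labels) && config$weights$class_ == 1 && mode != "prior") {
    if (mode == "unsup" || is.null(labels)) {
      stop("configuration error: lambda_class = 1 but no labels supplied")
    }
  }
  fit <- fit_factor_model(X, labels, batches, k = k, config = config, mode = mode)
  imp <- impute_zeros(X, fit)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mat_path <- file.path(out_dir,
                        if (dialect == "dense") "imputed.csv" else "imputed.mtx")
  write_matrix(imp$imputed, mat_path, dialect)
  trace_path <- file.path(out_dir, "trace.csv")
  utils::write.csv(fit$trace, trace_path, row.names = FALSE)
  manifest <- list(
    command = "impute",
    counts = normalizePath(counts_path),
    labels = if (!is.null(labels_path)) normalizePath(labels_path) else NULL,
    batches = if (!is.null(batches_path)) normalizePath(batches_path) else NULL,
    mode = fit$mode, k = fit$k, seed = config$seed,
    config = unclass(config)[setdiff(names(config), "weights")],
    lambdas = config$weights[c("nmf", "zinb", "zscore", "class_")],
    stop_epoch = fit$stop_epoch, stop_reason = fit$stop_reason,
    outputs = list(imputed = mat_path, trace = trace_path),
    version = as.character(utils::packageVersion("scprior"))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(list(fit = fit, imputation = imp,
                 paths = list(imputed = mat_path, trace = trace_path,
                              manifest = manifest_path)))
}

#' Read a run configuration file
#'
#' Flat key-value YAML (or JSON) mirroring [training_config()]; unknown keys
#' are rejected. Switches are given as `lambda_nmf`, `lambda_zinb`,
#' `lambda_zscore`, `lambda_class`.
#'
#' @param path Configuration file path.
#' @return A `scprior_config`.
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  lam <- list(nmf = 1, zinb = 1, zscore = 1, class_ = 1)
  key_map <- c(lambda_nmf = "nmf", lambda_zinb = "zinb",
               lambda_zscore = "zscore", lambda_class = "class_")
  for (kk in names(key_map)) {
    if (!is.null(vals[[kk]])) lam[[key_map[[kk]]]] <- vals[[kk]]
  }
  rest <- vals[setdiff(names(vals), names(key_map))]
  allowed <- c("eta0", "gamma", "t_decay", "eps_adam", "eps_loss",
               "patience", "max_epochs", "seed")
  unknown <- setdiff(names(rest), allowed)
  if (length(unknown) > 0) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(training_config, c(list(weights = do.call(loss_weights, lam)), rest))
}
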