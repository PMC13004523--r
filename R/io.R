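#' Read a cells-by-genes count matrix
#'
#' Loads either a Matrix Market coordinate file (with sibling `barcodes.tsv`
#' and `features.tsv` identifier files in the same directory) or a dense
#' delimited table (first row gene identifiers, first column cell identifiers,
#' comma or tab auto-detected), and validates it into the canonical
#' cells-by-genes orientation used throughout the package.
#'
#' Cells with a total count of zero are rejected at load: the size factor of
#' such a cell is zero and the depth-adjusted reconstruction degenerates, so
#' the loader fails fast with the offending cell named rather than emitting
#' NaNs downstream.
#'
#' @param path Path to a `.mtx` file or a dense `.csv`/`.tsv`/`.txt` table.
#' @param orientation Either `"cells-as-rows"` (default) or `"genes-as-rows"`,
#'   describing the on-disk layout. The returned matrix is always
#'   cells-by-genes.
#' @return A base numeric matrix, cells in rows (rownames = cell ids), genes
#'   in columns (colnames = gene ids), validated by [validate_counts()].
#' @export
read_counts <- function(path, orientation = c("cells-as-rows", "genes-as-rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("count file not found: ", path)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    mat <- .read_counts_mtx(path, orientation)
  } else {
    mat <- .read_counts_dense(path, orientation)
  }
  validate_counts(mat)
}

.read_counts_mtx <- function(path, orientation) {
  m <- as.matrix(Matrix::readMM(path))
  dir <- dirname(path)
  barcodes <- file.path(dir, "barcodes.tsv")
  features <- file.path(dir, "features.tsv")
  if (!file.exists(barcodes) || !file.exists(features)) {
    stop("Matrix Market input requires sibling 'barcodes.tsv' and 'features.tsv' files in ", dir)
  }
  cells <- readLines(barcodes)
  genes <- readLines(features)
  cells <- cells[nzchar(cells)]
  genes <- genes[nzchar(genes)]
  # keep only the first field if the annotation files carry extra columns
  cells <- vapply(strsplit(cells, "\t", fixed = TRUE), `[[`, character(1), 1L)
  genes <- vapply(strsplit(genes, "\t", fixed = TRUE), `[[`, character(1), 1L)
  if (orientation == "genes-as-rows") {
    if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
      stop("matrix dimensions (", nrow(m), "x", ncol(m),
           ") do not match features/barcodes lengths under genes-as-rows")
    }
    dimnames(m) <- list(genes, cells)
    m <- t(m)
  } else {
    if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
      stop("matrix dimensions (", nrow(m), "x", ncol(m),
           ") do not match barcodes/features lengths under cells-as-rows")
    }
    dimnames(m) <- list(cells, genes)
  }
  m
}

.read_counts_dense <- function(path, orientation) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (orientation == "genes-as-rows") m <- t(m)
  m
}

#' Validate a count matrix
#'
#' Checks the invariants every downstream stage relies on: numeric,
#' nonnegative, finite entries; unique non-empty cell and gene identifiers;
#' and a strictly positive total count for every cell.
#'
#' @param mat A numeric matrix with rownames (cells) and colnames (genes).
#' @param require_integer If `TRUE`, additionally require integer-valued
#'   entries (raw count input); imputed matrices are fractional and pass
#'   with the default `FALSE`.
#' @return The validated matrix, invisibly unchanged.
#' @export
validate_counts <- function(mat, require_integer = FALSE) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop("counts must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("count matrix must carry cell rownames and gene colnames")
  }
  if (anyDuplicated(rownames(mat))) stop("duplicate cell identifiers in count matrix")
  if (anyDuplicated(colnames(mat))) stop("duplicate gene identifiers in count matrix")
  if (any(!is.finite(mat))) stop("count matrix contains non-finite entries")
  if (any(mat < 0)) stop("count matrix contains negative entries")
  if (require_integer && any(mat != round(mat))) {
    stop("count matrix contains non-integer entries")
  }
  totals <- rowSums(mat)
  if (any(totals == 0)) {
    bad <- rownames(mat)[totals == 0]
    stop("cell(s) with zero total count: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  mat
}

#' Read a cell label table
#'
#' Reads a two-column delimited file (cell id, label; no header required,
#' but a `cell<tab>label` header line is tolerated) and returns the labels
#' aligned against a count matrix. Cells absent from the file are unlabeled
#' (`NA`), supporting partial-label protocols.
#'
#' @param path Path to a two-column TSV/CSV.
#' @param counts The companion count matrix (for id validation and ordering).
#' @return A tibble with columns `cell` and `label` (`NA` for unlabeled),
#'   one row per cell of `counts`, in matrix row order. Label levels are
#'   recorded in first-appearance (file) order in the `"types"` attribute.
#' @export
read_labels <- function(path, counts) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    out <- tibble::tibble(cell = rownames(counts), label = NA_character_)
    attr(out, "types") <- character(0)
    return(out)
  }
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  if (any(lengths(parts) < 2L)) stop("label file must have two columns (cell, label)")
  ids <- vapply(parts, `[[`, character(1), 1L)
  labs <- vapply(parts, `[[`, character(1), 2L)
  if (identical(tolower(ids[1]), "cell") || identical(tolower(labs[1]), "label")) {
    ids <- ids[-1]; labs <- labs[-1]
  }
  labels_from_vector(stats::setNames(labs, ids), counts)
}

#' Build a label table from a named vector
#'
#' @param x Named character vector: names are cell ids, values are labels.
#' @param counts The companion count matrix.
#' @return A tibble as in [read_labels()].
#' @export
labels_from_vector <- function(x, counts) {
  ids <- names(x)
  if (is.null(ids)) stop("label vector must be named by cell id")
  unknown <- setdiff(ids, rownames(counts))
  if (length(unknown) > 0) {
    stop("label(s) for unknown cell id(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (anyDuplicated(ids)) stop("duplicate cell ids in label table")
  lab <- rep(NA_character_, nrow(counts))
  names(lab) <- rownames(counts)
  lab[ids] <- as.character(x)
  out <- tibble::tibble(cell = rownames(counts), label = unname(lab))
  attr(out, "types") <- unique(as.character(x))
  out
}

#' Read a cell batch table
#'
#' Two-column delimited file (cell id, batch). Unlike labels, batch
#' assignment must cover every cell of the count matrix when supplied.
#'
#' @inheritParams read_labels
#' @return A tibble with columns `cell` and `batch`, one row per cell.
#' @export
read_batches <- function(path, counts) {
  tab <- read_labels(path, counts)
  names(tab)[names(tab) == "label"] <- "batch"
  if (anyNA(tab$batch)) {
    miss <- tab$cell[is.na(tab$batch)]
    stop("batch table must cover all cells; missing: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  attr(tab, "batches") <- attr(tab, "types")
  attr(tab, "types") <- NULL
  tab
}

#' Write a (possibly imputed) matrix to disk
#'
#' @param mat Numeric cells-by-genes matrix with dimnames; entries must be
#'   finite. Fractional (imputed) values are preserved to full double
#'   precision in both dialects.
#' @param path Output path. Dialect `"matrix-market"` writes `path` (a
#'   `.mtx` coordinate file) plus sibling `barcodes.tsv`/`features.tsv`;
#'   `"dense"` writes a single delimited table (tab if the extension is
#'   `.tsv`, comma otherwise).
#' @param dialect `"matrix-market"` or `"dense"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path, dialect = c("matrix-market", "dense")) {
  dialect <- match.arg(dialect)
  if (!is.matrix(mat) || !is.numeric(mat)) stop("input must be a numeric matrix")
  if (any(!is.finite(mat))) stop("cannot write non-finite entries")
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("matrix must carry cell rownames and gene colnames")
  }
  if (dialect == "matrix-market") {
    .write_mtx(mat, path)
  } else {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    df <- as.data.frame(mat, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = TRUE, col.names = NA)
  }
  invisible(path)
}

# Coordinate writer with full double precision (%.17g), cells as rows.
# Matrix::writeMM truncates reals; imputed matrices must round-trip to 1e-9.
.write_mtx <- function(mat, path) {
  idx <- which(mat != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate real general", con)
  writeLines(sprintf("%d %d %d", nrow(mat), ncol(mat), nrow(idx)), con)
  if (nrow(idx) > 0) {
    vals <- mat[idx]
    writeLines(sprintf("%d %d %.17g", idx[, 1], idx[, 2], vals), con)
  }
  dir <- dirname(path)
  writeLines(rownames(mat), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(mat), file.path(dir, "features.tsv"))
  invisible(path)
}

#' Write a label (or batch) table
#'
#' Writes the labeled rows of a label tibble as a headerless two-column TSV.
#'
#' @param labels A tibble with columns `cell` and `label` (or `batch`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  value_col <- setdiff(names(labels), "cell")[1]
  keep <- !is.na(labels[[value_col]])
  utils::write.table(labels[keep, c("cell", value_col)], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
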