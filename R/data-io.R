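#' Load an expression matrix from delimited text or a MATLAB archive
#'
#' Reads a samples x genes expression table plus binary class labels and
#' returns a validated [expression_dataset]. Delimited files must carry a
#' header row and a first column of identifiers. MATLAB \code{.mat} archives
#' (v5) are read through the system \code{python} interpreter's
#' \code{scipy.io.loadmat}; the expression matrix is taken as the largest 2-D
#' numeric array and the labels as a vector with two distinct values whose
#' length matches one of its dimensions.
#'
#' @param path path to a CSV/TSV file or a \code{.mat} archive.
#' @param orientation \code{"samples_in_rows"} (default) or
#'   \code{"genes_in_rows"}; the matrix is transposed as needed so that the
#'   returned dataset always has samples in rows.
#' @param label_source for delimited files: the name of the column
#'   (samples in rows) or row (genes in rows) holding the class labels, or
#'   the path of a side file with one label per line. Ignored for
#'   \code{.mat} archives, where labels are auto-detected.
#' @param delimiter field separator for delimited files; \code{","} by
#'   default, use \code{"\t"} for TSV.
#' @return An [expression_dataset] with labels recoded to \code{+1}/\code{-1}
#'   (first-seen category becomes \code{+1}).
#' @export
load_expression_matrix <- function(path,
                                   orientation = c("samples_in_rows", "genes_in_rows"),
                                   label_source = "label",
                                   delimiter = ",") {
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    kmg_stop("parse_error", sprintf("file not found: %s", path))
  if (grepl("\\.mat$", path, ignore.case = TRUE))
    return(load_mat_expression(path, orientation))

  raw <- tryCatch(
    utils::read.table(path, header = TRUE, sep = delimiter, row.names = 1,
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) kmg_stop("parse_error", sprintf(
      "failed to parse %s: %s", path, conditionMessage(e)))
  )

  side_file <- file.exists(label_source) && !dir.exists(label_source)
  labels <- NULL
  if (orientation == "genes_in_rows") {
    if (!side_file) {
      if (!label_source %in% rownames(raw))
        kmg_stop("parse_error", sprintf("label row '%s' not found", label_source))
      labels <- unlist(raw[label_source, ], use.names = FALSE)
      raw <- raw[setdiff(rownames(raw), label_source), , drop = FALSE]
    }
    mat <- coerce_numeric_matrix(raw, path)
    mat <- t(mat)
  } else {
    if (!side_file) {
      if (!label_source %in% colnames(raw))
        kmg_stop("parse_error", sprintf("label column '%s' not found", label_source))
      labels <- raw[[label_source]]
      raw <- raw[, setdiff(colnames(raw), label_source), drop = FALSE]
    }
    mat <- coerce_numeric_matrix(raw, path)
  }
  if (side_file) labels <- readLines(label_source)
  expression_dataset(mat, labels)
}

# Convert a read.table data.frame to a numeric matrix, naming the first
# offending cell on failure.
coerce_numeric_matrix <- function(df, path) {
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      suppress <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(suppress) & !is.na(col))[1]
      if (!is.na(bad))
        kmg_stop("parse_error", sprintf(
          "non-numeric value '%s' at row '%s', column '%s' of %s",
          col[bad], rownames(df)[bad], colnames(df)[j], path))
      df[[j]] <- suppress
    }
  }
  as.matrix(df)
}

# Read a v5 MATLAB archive via the system python (scipy.io.loadmat),
# round-tripping through temporary CSV files.
load_mat_expression <- function(path, orientation) {
  x_csv <- tempfile(fileext = ".csv")
  y_csv <- tempfile(fileext = ".csv")
  code <- paste(
    "import sys, numpy as np, scipy.io",
    sprintf("m = scipy.io.loadmat(r'%s')", path),
    "arrs = {k: np.asarray(v) for k, v in m.items() if not k.startswith('__')}",
    "mats = {k: v for k, v in arrs.items() if v.ndim == 2 and min(v.shape) > 1 and np.issubdtype(v.dtype, np.number)}",
    "if not mats: sys.exit('no 2-D numeric matrix found in archive')",
    "xk = max(mats, key=lambda k: mats[k].size)",
    "X = mats[xk].astype(float)",
    "vecs = {k: v.ravel() for k, v in arrs.items() if k != xk and v.size in X.shape and np.unique(v.ravel()).size == 2}",
    "if not vecs: sys.exit('no two-valued label vector matching the matrix was found')",
    "yk = sorted(vecs)[0]",
    "y = vecs[yk]",
    "if y.size == X.shape[1] and y.size != X.shape[0]: X = X.T",
    sprintf("np.savetxt(r'%s', X, delimiter=',')", x_csv),
    sprintf("np.savetxt(r'%s', np.asarray(y, dtype=float), delimiter=',')", y_csv),
    sep = "\n")
  status <- system2("python", c("-c", shQuote(code)), stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")) && attr(status, "status") != 0)
    kmg_stop("parse_error", sprintf(
      "failed to read MAT archive %s: %s", path, paste(status, collapse = "; ")))
  mat <- as.matrix(utils::read.csv(x_csv, header = FALSE))
  labels <- utils::read.csv(y_csv, header = FALSE)[[1]]
  dimnames(mat) <- NULL
  # scipy may have produced samples in either dimension; honor the caller's
  # declared orientation when label length is ambiguous.
  if (orientation == "genes_in_rows" && length(labels) == ncol(mat) &&
      length(labels) != nrow(mat)) mat <- t(mat)
  expression_dataset(mat, labels)
}

#' Standardize samples, then genes
#'
#' Z-scores each row (sample) of the expression matrix, then each column
#' (gene) of the result, the normalization applied to datasets before kernel
#' scoring. After the second pass every gene column has mean 0 and standard
#' deviation 1.
#'
#' @param ds an [expression_dataset].
#' @param sd_denom denominator convention for the standard deviation:
#'   \code{"n-1"} (sample sd, default) or \code{"n"}.
#' @return A standardized [expression_dataset].
#' @export
standardize_rows_then_columns <- function(ds, sd_denom = c("n-1", "n")) {
  sd_denom <- match.arg(sd_denom)
  x <- ds$values
  zpass <- function(mat, margin, what) {
    s <- apply(mat, margin, kmg_sd, denom = sd_denom)
    if (any(s == 0))
      kmg_stop("zero_variance", sprintf(
        "zero-variance %s at index %d", what, which(s == 0)[1]))
    mu <- apply(mat, margin, mean)
    if (margin == 1L) (mat - mu) / s else sweep(sweep(mat, 2L, mu), 2L, s, "/")
  }
  x <- zpass(x, 1L, "row (sample)")
  x <- zpass(x, 2L, "column (gene)")
  expression_dataset(x, ds$labels, ds$gene_ids, ds$sample_ids)
}

#' Threshold, filter and log-transform raw expression data
#'
#' The Dudoit-style preprocessing applied to raw (positive-valued) arrays:
#' (i) clamp values to \code{[floor, ceiling]}; (ii) drop genes whose
#' clamped max/min ratio is at most \code{ratio_min} or whose max - min
#' range is at most \code{diff_min} across samples; (iii) base-10
#' log-transform the surviving values. Gene order is preserved.
#'
#' @param ds an [expression_dataset] holding raw expression values.
#' @param floor,ceiling clamp bounds (defaults 100 and 16000).
#' @param ratio_min genes with max/min <= this are removed (default 5).
#' @param diff_min genes with max - min <= this are removed (default 500).
#' @return The filtered, log10-transformed [expression_dataset].
#' @export
dudoit_preprocess <- function(ds, floor = 100, ceiling = 16000,
                              ratio_min = 5, diff_min = 500) {
  stopifnot(floor > 0, ceiling > floor)
  x <- pmin(pmax(ds$values, floor), ceiling)
  mx <- apply(x, 2L, max)
  mn <- apply(x, 2L, min)
  keep <- which(mx / mn > ratio_min & mx - mn > diff_min)
  stopifnot(all(x > 0))
  out <- subset_genes(expression_dataset(log10(x), ds$labels, ds$gene_ids, ds$sample_ids),
                      keep)
  out
}

#' Keep the top genes by Fisher's ratio
#'
#' Scores every gene with [fisher_scores()] and retains the \code{k} highest
#' scoring genes (ties broken toward the lower gene index), preserving their
#' original order in the matrix.
#'
#' @param ds an [expression_dataset] with both classes present.
#' @param k number of genes to retain (\code{k <= m}).
#' @return The reduced [expression_dataset].
#' @export
fisher_prescreen <- function(ds, k) {
  assert_two_class(ds)
  m <- ncol(ds$values)
  if (k > m)
    kmg_stop("bad_k", sprintf("k (%d) exceeds the number of genes (%d)", k, m))
  sc <- fisher_scores(ds)
  top <- order(-sc, seq_along(sc))[seq_len(k)]
  subset_genes(ds, sort(top))
}
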