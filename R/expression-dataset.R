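#' Construct a two-class expression dataset
#'
#' The container every stage of the package operates on: a numeric matrix of
#' expression values with samples in rows and genes in columns, plus a binary
#' class label per sample.
#'
#' Labels are recoded to \code{+1}/\code{-1}. If the supplied labels are
#' already numeric in \code{\{-1, +1\}} they are kept as given; otherwise the
#' first-seen category maps to \code{+1} and the second to \code{-1}.
#'
#' @param values numeric matrix, n samples x m genes; all entries finite.
#' @param labels vector of length n with exactly two distinct values.
#' @param gene_ids optional character vector of m gene identifiers.
#' @param sample_ids optional character vector of n sample identifiers.
#' @return An object of class \code{expression_dataset}: a list with elements
#'   \code{values}, \code{labels} (integer \code{+1}/\code{-1}),
#'   \code{gene_ids} and \code{sample_ids}.
#' @examples
#' ds <- expression_dataset(matrix(rnorm(20), 4, 5), c("A", "A", "B", "B"))
#' ds$labels
#' @export
expression_dataset <- function(values, labels, gene_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    kmg_stop("parse_error", "`values` must be a numeric matrix")
  if (anyNA(values) || !all(is.finite(values)))
    kmg_stop("parse_error", "expression matrix contains missing or non-finite entries")
  n <- nrow(values); m <- ncol(values)
  if (length(labels) != n)
    kmg_stop("dim_mismatch", sprintf(
      "length of labels (%d) does not match number of samples (%d)", length(labels), n))
  labels <- recode_labels(labels)
  gene_ids <- gene_ids %||% colnames(values) %||% sprintf("gene_%d", seq_len(m))
  sample_ids <- sample_ids %||% rownames(values) %||% sprintf("sample_%d", seq_len(n))
  if (length(gene_ids) != m)
    kmg_stop("dim_mismatch", sprintf(
      "length of gene_ids (%d) does not match number of genes (%d)", length(gene_ids), m))
  if (length(sample_ids) != n)
    kmg_stop("dim_mismatch", "length of sample_ids does not match number of samples")
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(
    list(values = values, labels = labels,
         gene_ids = as.character(gene_ids), sample_ids = as.character(sample_ids)),
    class = "expression_dataset"
  )
}

recode_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  u <- unique(labels)
  if (length(u) != 2L)
    kmg_stop("label_classes", sprintf(
      "labels must contain exactly 2 classes, found %d", length(u)))
  if (is.numeric(labels) && setequal(u, c(-1, 1))) return(as.integer(labels))
  ifelse(labels == u[[1L]], 1L, -1L)
}

# Both classes present and non-degenerate shape; used by selectors/evaluators.
assert_two_class <- function(ds) {
  if (sum(ds$labels == 1L) < 1L || sum(ds$labels == -1L) < 1L)
    kmg_stop("label_classes", "dataset must contain samples from both classes")
  invisible(ds)
}

# Subset samples (multiset indices allowed, for bootstrap resampling).
subset_samples <- function(ds, idx) {
  structure(
    list(values = ds$values[idx, , drop = FALSE], labels = ds$labels[idx],
         gene_ids = ds$gene_ids, sample_ids = ds$sample_ids[idx]),
    class = "expression_dataset"
  )
}

# Subset genes, preserving the given order.
subset_genes <- function(ds, idx) {
  structure(
    list(values = ds$values[, idx, drop = FALSE], labels = ds$labels,
         gene_ids = ds$gene_ids[idx], sample_ids = ds$sample_ids),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "expression_dataset: %d samples x %d genes (%d positive / %d negative)\n",
    nrow(x$values), ncol(x$values), sum(x$labels == 1L), sum(x$labels == -1L)))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)
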