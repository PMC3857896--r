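#' Kernel configuration
#'
#' @param kind \code{"linear"} or \code{"rbf"} (Gaussian radial basis
#'   function).
#' @param sigma width of the Gaussian kernel, \code{K(x, y) =
#'   exp(-||x - y||^2 / sigma)}. Required (and must be positive) when
#'   \code{kind = "rbf"}; ignored for the linear kernel.
#' @return An object of class \code{kernel_spec}.
#' @examples
#' kernel_spec("rbf", sigma = 0.5)
#' @export
kernel_spec <- function(kind = c("linear", "rbf"), sigma = NULL) {
  kind <- match.arg(kind)
  if (kind == "rbf") {
    if (is.null(sigma) || !is.finite(sigma) || sigma <= 0)
      kmg_stop("bad_sigma", "rbf kernel requires a positive, finite sigma")
  } else {
    sigma <- NULL
  }
  structure(list(kind = kind, sigma = sigma), class = "kernel_spec")
}

#' Compute a Gram matrix
#'
#' Builds the n x n matrix of pairwise sample similarities. Linear:
#' \code{K_ij = <x_i, x_j>} (not yet normalized; see
#' [normalize_linear_columns()]). Gaussian RBF: \code{K_ij =
#' exp(-||x_i - x_j||^2 / sigma)}, which has unit diagonal by construction
#' and needs no normalization.
#'
#' @param X numeric matrix, n samples x d features, finite entries,
#'   \code{n >= 2}.
#' @param spec a [kernel_spec()].
#' @return An object of class \code{gram_matrix}: list with \code{entries}
#'   (n x n), \code{normalized} (logical), \code{spec}, and
#'   \code{degenerate} (indices of zeroed columns, see
#'   [normalize_linear_columns()]).
#' @export
compute_gram <- function(X, spec) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) kmg_stop("bad_input", "need at least 2 samples")
  if (anyNA(X) || !all(is.finite(X)))
    kmg_stop("bad_input", "non-finite entries in input matrix")
  stopifnot(inherits(spec, "kernel_spec"))
  if (spec$kind == "linear") {
    entries <- tcrossprod(X)
    normalized <- FALSE
  } else {
    sq <- rowSums(X^2)
    d2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(X), 0)
    entries <- exp(-d2 / spec$sigma)
    diag(entries) <- 1
    normalized <- TRUE
  }
  structure(list(entries = entries, normalized = normalized, spec = spec,
                 degenerate = integer(0)),
            class = "gram_matrix")
}

#' Normalize linear-kernel columns to unit self-similarity
#'
#' Divides every element of column \code{j} by the diagonal entry
#' \code{K_jj}, so that each sample's self-similarity becomes 1 before the
#' separability statistic is applied. The result is generally no longer
#' symmetric. Columns with \code{K_jj < 1e-12} are zeroed and recorded in
#' \code{degenerate} rather than raising an error.
#'
#' @param K an unnormalized linear \code{gram_matrix}.
#' @return The column-normalized \code{gram_matrix}.
#' @export
normalize_linear_columns <- function(K) {
  stopifnot(inherits(K, "gram_matrix"))
  if (K$spec$kind != "linear")
    kmg_stop("bad_input", "column normalization applies to linear kernels only")
  if (K$normalized)
    kmg_stop("bad_input", "gram matrix is already normalized")
  d <- diag(K$entries)
  deg <- which(d < 1e-12)
  d[deg] <- 1
  entries <- sweep(K$entries, 2L, d, "/")
  entries[, deg] <- 0
  structure(list(entries = entries, normalized = TRUE, spec = K$spec,
                 degenerate = sort(union(K$degenerate, deg))),
            class = "gram_matrix")
}

#' Separability of one sample from one kernel column
#'
#' Splits the n similarities in a kernel-matrix column into the same-class
#' population (samples sharing the column sample's label, self-similarity
#' included) and the opposite-class population, and returns the t-like score
#' \deqn{S = (mean(P_{same}) - mean(P_{opp})) / (sd(P_{same}) + sd(P_{opp}))}
#' with sample (n-1) standard deviations. A large positive score marks a
#' discriminant sample; a negative score marks a sample more similar to the
#' opposite class than to its own.
#'
#' If the two standard deviations sum to less than \code{1e-12} the score is
#' defined as 0 and the attribute \code{degenerate} is set (no epsilon is
#' ever added to the denominator).
#'
#' @param column numeric vector of n similarities (a kernel-matrix column).
#' @param self_index position of the column's own sample within the column.
#' @param labels vector of n labels in \code{\{+1, -1\}}, both classes
#'   present.
#' @param sd_denom \code{"n-1"} (default) or \code{"n"}.
#' @return The score, a single number with logical attribute
#'   \code{degenerate}.
#' @export
column_separability <- function(column, self_index, labels,
                                sd_denom = c("n-1", "n")) {
  sd_denom <- match.arg(sd_denom)
  if (!all(is.finite(column))) kmg_stop("bad_input", "non-finite column entries")
  if (length(unique(labels)) != 2L)
    kmg_stop("label_classes", "labels must contain both classes")
  same <- labels == labels[self_index]
  p_same <- column[same]
  p_opp <- column[!same]
  den <- kmg_sd(p_same, sd_denom) + kmg_sd(p_opp, sd_denom)
  if (den < 1e-12)
    return(structure(0, degenerate = TRUE))
  structure((mean(p_same) - mean(p_opp)) / den, degenerate = FALSE)
}

#' Separability of a whole classification problem
#'
#' Applies [column_separability()] to every column of a (normalized) Gram
#' matrix and sums the per-sample scores into the problem-level score M, the
#' quantity the gene selectors maximize.
#'
#' @param K a \code{gram_matrix}, either RBF or a column-normalized linear
#'   kernel.
#' @param labels vector of n labels in \code{\{+1, -1\}}.
#' @param sd_denom \code{"n-1"} (default) or \code{"n"}.
#' @param warn warn when degenerate columns are encountered (default TRUE).
#' @return An object of class \code{separability_result}: list with
#'   \code{per_sample} (n scores), \code{total} (their sum) and
#'   \code{degenerate_columns}.
#' @export
problem_separability <- function(K, labels, sd_denom = c("n-1", "n"),
                                 warn = TRUE) {
  sd_denom <- match.arg(sd_denom)
  stopifnot(inherits(K, "gram_matrix"))
  if (!K$normalized)
    kmg_stop("bad_input", "linear gram matrix must be column-normalized first")
  if (length(labels) != nrow(K$entries))
    kmg_stop("dim_mismatch", "labels do not match gram matrix size")
  if (length(unique(labels)) != 2L)
    kmg_stop("label_classes", "labels must contain both classes")
  sc <- sep_scores(K$entries, labels, denom = sd_denom)
  degenerate <- sort(union(K$degenerate, sc$degenerate))
  if (warn && length(degenerate))
    warning(sprintf("%d degenerate column(s) scored as 0", length(degenerate)),
            call. = FALSE)
  structure(list(per_sample = sc$per_sample, total = sum(sc$per_sample),
                 degenerate_columns = degenerate),
            class = "separability_result")
}

#' @export
print.separability_result <- function(x, ...) {
  cat(sprintf("separability_result: total M = %.6g over %d samples (%d degenerate)\n",
              x$total, length(x$per_sample), length(x$degenerate_columns)))
  invisible(x)
}
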