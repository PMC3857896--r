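#' Generate a synthetic two-class expression dataset with planted signal
#'
#' Emulates a standardized microarray study: a samples x genes matrix of
#' Gaussian noise in which a known subset of genes carries class signal.
#' Linear (mean-shift) DEGs have class means at +delta/2 and -delta/2 with
#' unit within-class spread, the regime a linear kernel or Fisher's ratio
#' detects. Nonlinear (variance-shift) DEGs have equal class means but a
#' class-spread ratio of rho (class + spread 1, class - spread rho), a
#' signal invisible to mean-based statistics but visible to an RBF kernel.
#' All remaining genes are exchangeable standard-normal nulls. The matrix is
#' then passed through [standardize_rows_then_columns()], as real data would
#' be.
#'
#' Planted genes occupy the leading columns (linear DEGs first, then
#' nonlinear); their indices are recorded in the returned truth object.
#'
#' Defaults correspond to a moderate-size study: 30 + 30 samples, 5
#' mean-shift DEGs with a 3-sd class separation among 200 null genes.
#'
#' @param n_pos,n_neg samples per class (each \code{>= 2}).
#' @param m total number of genes.
#' @param n_linear_deg number of mean-shift DEGs.
#' @param delta class-mean separation of linear DEGs in within-class sd
#'   units (\code{>= 0}).
#' @param n_nonlinear_deg number of variance-shift DEGs.
#' @param rho class spread ratio of nonlinear DEGs (\code{>= 1}).
#' @param seed integer seed; the output is deterministic given the seed.
#' @return A list with elements \code{dataset} (an [expression_dataset],
#'   standardized) and \code{truth} (class \code{synthetic_truth}: lists of
#'   \code{linear_deg_indices}, \code{nonlinear_deg_indices},
#'   \code{null_indices}, plus \code{delta}, \code{rho}, \code{seed}).
#' @examples
#' sim <- generate_dataset(n_pos = 5, n_neg = 5, m = 20, n_linear_deg = 2,
#'                         delta = 3, seed = 1)
#' sim$truth$linear_deg_indices
#' @export
generate_dataset <- function(n_pos = 30L, n_neg = 30L, m = 205L,
                             n_linear_deg = 5L, delta = 3,
                             n_nonlinear_deg = 0L, rho = 1,
                             seed = 1L) {
  if (n_pos < 2L || n_neg < 2L)
    kmg_stop("bad_input", "need at least 2 samples per class")
  if (n_linear_deg + n_nonlinear_deg > m)
    kmg_stop("bad_input", "more planted DEGs than genes")
  if (delta < 0) kmg_stop("bad_input", "delta must be non-negative")
  if (rho < 1) kmg_stop("bad_input", "rho must be at least 1")
  m <- as.integer(m)
  n_linear_deg <- as.integer(n_linear_deg)
  n_nonlinear_deg <- as.integer(n_nonlinear_deg)
  n <- n_pos + n_neg
  labels <- c(rep(1L, n_pos), rep(-1L, n_neg))
  pos <- labels == 1L

  x <- withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n * m), n, m)
    if (n_linear_deg > 0L) {
      lin <- seq_len(n_linear_deg)
      x[pos, lin] <- x[pos, lin] + delta / 2
      x[!pos, lin] <- x[!pos, lin] - delta / 2
    }
    if (n_nonlinear_deg > 0L) {
      nl <- n_linear_deg + seq_len(n_nonlinear_deg)
      x[!pos, nl] <- x[!pos, nl] * rho
    }
    x
  })

  ds <- expression_dataset(
    x, labels,
    gene_ids = sprintf("gene_%03d", seq_len(m)),
    sample_ids = sprintf("sample_%02d", seq_len(n)))
  ds <- standardize_rows_then_columns(ds)

  truth <- structure(list(
    linear_deg_indices = seq_len(n_linear_deg),
    nonlinear_deg_indices = n_linear_deg + seq_len(n_nonlinear_deg),
    null_indices = setdiff(seq_len(m), seq_len(n_linear_deg + n_nonlinear_deg)),
    delta = delta, rho = rho, seed = as.integer(seed)),
    class = "synthetic_truth")

  list(dataset = ds, truth = truth)
}

#' Write a synthetic dataset and its truth table to disk
#'
#' The expression matrix goes to CSV in the same dialect
#' [load_expression_matrix()] reads (samples in rows, a \code{label}
#' column); the truth table goes to JSON.
#'
#' @param sim a list as returned by [generate_dataset()].
#' @param data_path CSV output path for the dataset.
#' @param truth_path optional JSON output path for the truth table.
#' @return \code{data_path}, invisibly.
#' @export
write_synthetic <- function(sim, data_path, truth_path = NULL) {
  ds <- sim$dataset
  df <- data.frame(id = ds$sample_ids, label = ds$labels,
                   ds$values, check.names = FALSE)
  utils::write.csv(df, data_path, row.names = FALSE)
  if (!is.null(truth_path))
    jsonlite::write_json(unclass(sim$truth), truth_path, auto_unbox = TRUE)
  invisible(data_path)
}
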