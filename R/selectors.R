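#' Rank genes by kernel-matrix separability (KMGS)
#'
#' For each gene, forms the one-dimensional classification problem given by
#' that gene's values across samples, builds its Gram matrix (column-
#' normalizing linear kernels), and scores the problem with
#' [problem_separability()]. Genes are ranked by descending problem
#' separability M; ties break toward the lower gene index.
#'
#' @param ds a standardized [expression_dataset] with both classes present.
#' @param spec a [kernel_spec()].
#' @param sd_denom \code{"n-1"} (default) or \code{"n"}.
#' @return An object of class \code{gene_ranking}: list with \code{scores}
#'   (one M per gene), \code{order} (gene indices by descending score),
#'   \code{gene_ids} and \code{spec}.
#' @export
kmgs_rank <- function(ds, spec, sd_denom = c("n-1", "n")) {
  sd_denom <- match.arg(sd_denom)
  assert_two_class(ds)
  stopifnot(inherits(spec, "kernel_spec"))
  X <- ds$values
  n <- nrow(X); m <- ncol(X)
  same <- outer(ds$labels, ds$labels, "==")
  scores <- numeric(m)
  fully_degenerate <- logical(m)
  for (g in seq_len(m)) {
    E <- single_gene_gram(X[, g], spec)
    sc <- sep_scores(E, ds$labels, same, sd_denom)
    scores[g] <- sum(sc$per_sample)
    fully_degenerate[g] <- length(sc$degenerate) == n
  }
  if (all(fully_degenerate))
    kmg_stop("degenerate", "all genes produced fully degenerate kernel columns")
  structure(list(scores = scores,
                 order = order(-scores, seq_len(m)),
                 gene_ids = ds$gene_ids, spec = spec),
            class = "gene_ranking")
}

# Normalized similarity matrix of the 1-gene problem.
single_gene_gram <- function(x, spec) {
  if (spec$kind == "linear") {
    E <- tcrossprod(x)
    d <- x^2
    deg <- d < 1e-12
    d[deg] <- 1
    E <- sweep(E, 2L, d, "/")
    E[, deg] <- 0
    E
  } else {
    exp(-outer(x, x, "-")^2 / spec$sigma)
  }
}

#' Greedy forward selection of a gene subset (KMSFS)
#'
#' Grows a DEG set one gene at a time. An n x n accumulator A holds the
#' pairwise statistic of the genes selected so far: accumulated inner
#' products for the linear kernel, accumulated squared coordinate
#' differences for the RBF kernel. At each step every remaining candidate k
#' is scored by converting \code{A + contribution(k)} into a Gram matrix
#' (linear: column-normalize; RBF: \code{exp(-./sigma)}) and evaluating
#' [problem_separability()]; the argmax joins the set (ties break toward the
#' lower gene index) and its contribution is folded into A. This incremental
#' update makes each candidate evaluation O(n^2) while remaining exactly
#' equivalent to rebuilding the subset Gram matrix from scratch.
#'
#' @param ds a standardized [expression_dataset].
#' @param spec a [kernel_spec()].
#' @param T number of genes to select (\code{T <= m}).
#' @param sd_denom \code{"n-1"} (default) or \code{"n"}.
#' @return An object of class \code{selection_trace}: list with
#'   \code{selected} (T gene indices in chronological order),
#'   \code{step_scores} (winning M at each step), \code{accumulator} (final
#'   A), \code{gene_ids} and \code{spec}.
#' @export
kmsfs_select <- function(ds, spec, T, sd_denom = c("n-1", "n")) {
  sd_denom <- match.arg(sd_denom)
  assert_two_class(ds)
  stopifnot(inherits(spec, "kernel_spec"))
  X <- ds$values
  n <- nrow(X); m <- ncol(X)
  if (T > m) kmg_stop("bad_k", sprintf("T (%d) exceeds the number of genes (%d)", T, m))
  if (T < 1L) kmg_stop("bad_k", "T must be at least 1")
  same <- outer(ds$labels, ds$labels, "==")
  linear <- spec$kind == "linear"
  contribution <- function(x) if (linear) tcrossprod(x) else outer(x, x, "-")^2

  A <- matrix(0, n, n)
  remaining <- seq_len(m)
  selected <- integer(0)
  step_scores <- numeric(0)
  for (t in seq_len(T)) {
    best <- NA_integer_
    best_score <- -Inf
    for (k in remaining) {
      B <- A + contribution(X[, k])
      E <- if (linear) {
        d <- diag(B)
        deg <- d < 1e-12
        d[deg] <- 1
        Bn <- sweep(B, 2L, d, "/")
        Bn[, deg] <- 0
        Bn
      } else {
        exp(-B / spec$sigma)
      }
      tot <- sum(sep_scores(E, ds$labels, same, sd_denom)$per_sample)
      if (tot > best_score) {        # strict: ties keep the lower index
        best_score <- tot
        best <- k
      }
    }
    selected <- c(selected, best)
    step_scores <- c(step_scores, best_score)
    A <- A + contribution(X[, best])
    remaining <- setdiff(remaining, best)
  }
  structure(list(selected = selected, step_scores = step_scores,
                 accumulator = A, gene_ids = ds$gene_ids, spec = spec),
            class = "selection_trace")
}

#' Fisher's ratio of every gene
#'
#' The classical filter score
#' \deqn{F_g = (\mu_g^+ - \mu_g^-)^2 / ((\sigma_g^+)^2 + (\sigma_g^-)^2)}
#' with class-wise means and sample (n-1) standard deviations across
#' samples; larger means more discriminant. When both class variances are
#' zero the score is \code{Inf} if the class means differ and 0 otherwise.
#'
#' @param ds an [expression_dataset] with both classes present.
#' @return Numeric vector of m scores.
#' @export
fisher_scores <- function(ds) {
  assert_two_class(ds)
  pos <- ds$labels == 1L
  class_stats <- function(Xc) {
    mu <- colMeans(Xc)
    v <- if (nrow(Xc) > 1L) {
      colSums((Xc - rep(mu, each = nrow(Xc)))^2) / (nrow(Xc) - 1L)
    } else {
      numeric(ncol(Xc))
    }
    list(mu = mu, v = v)
  }
  p <- class_stats(ds$values[pos, , drop = FALSE])
  q <- class_stats(ds$values[!pos, , drop = FALSE])
  num <- (p$mu - q$mu)^2
  den <- p$v + q$v
  unname(ifelse(den == 0, ifelse(num > 0, Inf, 0), num / den))
}

#' @export
print.gene_ranking <- function(x, ...) {
  k <- min(5L, length(x$order))
  cat(sprintf("gene_ranking (%s kernel): %d genes; top %d: %s\n",
              x$spec$kind, length(x$scores), k,
              paste(x$gene_ids[x$order[seq_len(k)]], collapse = ", ")))
  invisible(x)
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("selection_trace (%s kernel): %d genes selected: %s\n",
              x$spec$kind, length(x$selected),
              paste(x$gene_ids[x$selected], collapse = ", ")))
  invisible(x)
}

#' Serialize a gene ranking or selection trace
#'
#' Writes a CSV with columns \code{gene_id}, \code{rank}/\code{step} and
#' \code{score}, or a JSON equivalent.
#'
#' @param x a \code{gene_ranking} or \code{selection_trace}.
#' @param path output path; format chosen by extension (\code{.csv} or
#'   \code{.json}).
#' @return \code{path}, invisibly.
#' @export
write_selection <- function(x, path) {
  df <- if (inherits(x, "gene_ranking")) {
    data.frame(gene_id = x$gene_ids[x$order],
               rank = seq_along(x$order),
               score = x$scores[x$order])
  } else if (inherits(x, "selection_trace")) {
    data.frame(gene_id = x$gene_ids[x$selected],
               step = seq_along(x$selected),
               score = x$step_scores)
  } else {
    kmg_stop("bad_input", "x must be a gene_ranking or selection_trace")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
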