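#' Friedman rank-sum test on a block x treatment error matrix
#'
#' Non-parametric alternative to repeated-measures ANOVA. Each block's k
#' values are ranked ascending (smaller error = better = rank 1, ties get
#' average ranks); the test statistic is
#' \deqn{\chi^2 = \frac{12N}{k(k+1)} \sum_j (\bar R_j - (k+1)/2)^2}
#' referred to a chi-square distribution with k-1 degrees of freedom.
#'
#' @param errors numeric matrix, N blocks (e.g. gene counts) x k treatments
#'   (e.g. parameter settings); finite entries, \code{N >= 2}, \code{k >= 2}.
#' @return An object of class \code{friedman_result}: list with
#'   \code{mean_ranks}, \code{statistic}, \code{df}, \code{p_value},
#'   \code{N}, \code{k}.
#' @export
friedman_test <- function(errors) {
  errors <- as.matrix(errors)
  if (anyNA(errors) || !all(is.finite(errors)))
    kmg_stop("bad_input", "non-finite entries in error matrix")
  N <- nrow(errors); k <- ncol(errors)
  if (N < 2L || k < 2L)
    kmg_stop("bad_input", "need at least 2 blocks and 2 treatments")
  ranks <- t(apply(errors, 1L, rank))
  mean_ranks <- colMeans(ranks)
  statistic <- (12 * N / (k * (k + 1))) * sum((mean_ranks - (k + 1) / 2)^2)
  structure(list(mean_ranks = as.numeric(mean_ranks), statistic = statistic,
                 df = k - 1L,
                 p_value = stats::pchisq(statistic, df = k - 1L, lower.tail = FALSE),
                 N = N, k = k),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman chi-square = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat("mean ranks:", paste(sprintf("%.3f", x$mean_ranks), collapse = ", "), "\n")
  invisible(x)
}

#' Holm post-hoc selection of settings not worse than the best
#'
#' Compares the best-ranked setting against each of the other k-1 settings
#' with \deqn{z_j = (\bar R_j - \bar R_{best}) / \sqrt{k(k+1)/(6N)}}
#' (two-sided normal p-values) and applies Holm's step-down procedure at
#' level \code{alpha}. Settings whose comparison is not rejected are kept,
#' together with the best one. If the Friedman test itself did not reject at
#' \code{alpha}, all settings are returned.
#'
#' @param result a \code{friedman_result}.
#' @param N number of blocks (defaults to \code{result$N}).
#' @param alpha family-wise error level (default 0.05).
#' @return Integer vector of setting indices (the \code{best_set}).
#' @export
holm_select <- function(result, N = result$N, alpha = 0.05) {
  stopifnot(inherits(result, "friedman_result"))
  k <- result$k
  if (result$p_value > alpha) return(seq_len(k))
  best <- order(result$mean_ranks, seq_len(k))[1L]
  others <- setdiff(seq_len(k), best)
  se <- sqrt(k * (k + 1) / (6 * N))
  z <- (result$mean_ranks[others] - result$mean_ranks[best]) / se
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  m <- length(p)
  ord <- order(p, seq_along(p))
  rejected <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= alpha / (m - i + 1)) {
      rejected[ord[i]] <- TRUE
    } else {
      break   # step-down stops at the first non-rejection
    }
  }
  sort(c(best, others[!rejected]))
}

#' Grid search over kernel width and SVM regularization
#'
#' Runs [external_b632plus_curve()] for every (sigma, C) setting on the same
#' bootstrap plan (so the G per-gene-count errors are repeated measures),
#' compares settings with [friedman_test()] plus [holm_select()], and
#' returns the best-ranked member of the selected set; ties break toward the
#' smaller sigma, then the smaller C. Linear-kernel selectors ignore sigma
#' and are gridded over C alone.
#'
#' @param ds an [expression_dataset].
#' @param selector \code{"kmgs"}, \code{"kmsfs"} or \code{"fisher"}.
#' @param kind kernel kind for the kernel selectors, \code{"linear"} or
#'   \code{"rbf"}.
#' @param sigma_grid RBF widths to try (default \code{10^(-5:5)}).
#' @param C_grid SVM regularization values to try (default \code{10^(-3:3)}).
#' @param plan a [balanced_bootstrap()] plan.
#' @param G number of gene counts per curve (default 100).
#' @param alpha level for the Friedman/Holm selection (default 0.05).
#' @param sd_denom \code{"n-1"} (default) or \code{"n"}.
#' @return An object of class \code{tuning_result}: list with \code{best}
#'   (row of \code{settings}), \code{settings} (data.frame sigma/C/
#'   mean_rank/in_best_set), \code{errors} (G x k matrix of B.632+ errors),
#'   \code{friedman}, \code{best_set}.
#' @export
grid_search <- function(ds, selector, kind = c("linear", "rbf"),
                        sigma_grid = 10^(-5:5), C_grid = 10^(-3:3),
                        plan, G = 100L, alpha = 0.05, sd_denom = "n-1") {
  kind <- match.arg(kind)
  uses_sigma <- kind == "rbf" && (is.function(selector) ||
                                  selector %in% c("kmgs", "kmsfs"))
  settings <- if (uses_sigma) {
    expand.grid(sigma = sigma_grid, C = C_grid, KEEP.OUT.ATTRS = FALSE)
  } else {
    data.frame(sigma = NA_real_, C = C_grid)
  }
  if (nrow(settings) == 0L) kmg_stop("bad_input", "empty parameter grid")
  k <- nrow(settings)

  errors <- matrix(NA_real_, G, k)
  for (j in seq_len(k)) {
    spec <- if (uses_sigma) {
      kernel_spec("rbf", sigma = settings$sigma[j])
    } else {
      kernel_spec("linear")
    }
    curve <- external_b632plus_curve(ds, selector, spec = spec,
                                     svm_C = settings$C[j], G = G, plan = plan,
                                     sd_denom = sd_denom)
    errors[, j] <- curve$b632plus
  }

  if (k == 1L) {
    settings$mean_rank <- 1
    settings$in_best_set <- TRUE
    return(structure(list(best = settings[1L, ], settings = settings,
                          errors = errors, friedman = NULL,
                          best_set = 1L),
                     class = "tuning_result"))
  }

  fr <- friedman_test(errors)
  best_set <- holm_select(fr, alpha = alpha)
  settings$mean_rank <- fr$mean_ranks
  settings$in_best_set <- seq_len(k) %in% best_set
  cand <- settings[best_set, , drop = FALSE]
  ord <- order(cand$mean_rank,
               if (uses_sigma) cand$sigma else rep(0, nrow(cand)),
               cand$C)
  best <- cand[ord[1L], , drop = FALSE]
  structure(list(best = best, settings = settings, errors = errors,
                 friedman = fr, best_set = best_set),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat("tuning_result: best setting\n")
  print(x$best, row.names = FALSE)
  invisible(x)
}

#' Write a tuning report as CSV
#'
#' One row per setting with its mean rank and membership of the best set.
#'
#' @param x a \code{tuning_result}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_tuning_report <- function(x, path) {
  utils::write.csv(x$settings, path, row.names = FALSE)
  invisible(path)
}
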