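#' Balanced bootstrap resampling plan
#'
#' Draws B bootstrap sets of size n with the balance constraint that every
#' sample occurs exactly B times in total across the B sets, which reduces
#' the variance of the error estimate relative to independent resampling.
#' The plan is built by permuting the multiset holding each index B times
#' and cutting it into B blocks of n; if any block has an empty out-of-bag
#' complement or a single-class in-bag sample, the whole multiset is
#' re-permuted (at most \code{max_attempts} times).
#'
#' @param n number of samples (\code{n >= 4}).
#' @param B number of bootstrap sets (default 200).
#' @param labels vector of n class labels in \code{\{+1, -1\}}.
#' @param seed integer seed; the plan is deterministic given the seed.
#' @param max_attempts bound on re-permutations (default 1000).
#' @return An object of class \code{bootstrap_plan}: list with \code{B},
#'   \code{n}, \code{sets} (list of B index vectors of length n),
#'   \code{seed}.
#' @export
balanced_bootstrap <- function(n, B = 200L, labels, seed, max_attempts = 1000L) {
  if (n < 4L) kmg_stop("bad_input", "need at least 4 samples")
  if (B < 1L) kmg_stop("bad_input", "B must be at least 1")
  if (length(labels) != n) kmg_stop("dim_mismatch", "labels must have length n")
  pool <- rep(seq_len(n), times = B)
  sets <- withr::with_seed(seed, {
    out <- NULL
    for (attempt in seq_len(max_attempts)) {
      perm <- sample(pool)
      blocks <- split(perm, rep(seq_len(B), each = n))
      ok <- vapply(blocks, function(b) {
        length(unique(b)) < n && length(unique(labels[b])) == 2L
      }, logical(1))
      if (all(ok)) { out <- blocks; break }
    }
    out
  })
  if (is.null(sets))
    kmg_stop("unsatisfiable_plan", sprintf(
      "no balanced plan satisfying the invariants found in %d attempts", max_attempts))
  structure(list(B = as.integer(B), n = as.integer(n),
                 sets = unname(sets), seed = as.integer(seed)),
            class = "bootstrap_plan")
}

#' @export
print.bootstrap_plan <- function(x, ...) {
  cat(sprintf("bootstrap_plan: B = %d sets of n = %d (seed %d)\n", x$B, x$n, x$seed))
  invisible(x)
}

#' Serialize a bootstrap plan as JSON
#'
#' @param plan a \code{bootstrap_plan}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bootstrap_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' No-information error rate
#'
#' The expected error if labels and predictions were independent:
#' \deqn{\gamma = \sum_k p_k (1 - q_k)} with \code{p_k} the observed label
#' proportions and \code{q_k} the predicted-label proportions.
#'
#' @param labels observed class labels.
#' @param predictions predicted class labels (same length).
#' @return gamma, a number in \code{[0, 1]}.
#' @export
no_information_rate <- function(labels, predictions) {
  if (length(labels) == 0L || length(predictions) == 0L)
    kmg_stop("bad_input", "empty label or prediction vector")
  if (length(labels) != length(predictions))
    kmg_stop("dim_mismatch", "labels and predictions differ in length")
  classes <- unique(c(labels, predictions))
  p <- vapply(classes, function(k) mean(labels == k), numeric(1))
  q <- vapply(classes, function(k) mean(predictions == k), numeric(1))
  sum(p * (1 - q))
}

#' Combine error components into the B.632+ estimate
#'
#' Standard .632+ blending of the apparent (resubstitution) error and the
#' leave-one-out bootstrap error, with the weight driven by the relative
#' overfitting rate against the no-information rate:
#' \code{err1' = min(err1, gamma)}; \code{R = (err1' - err_bar) /
#' (gamma - err_bar)} when \code{gamma > err_bar} and \code{err1' > err_bar},
#' else 0, clipped to \code{[0, 1]}; \code{w = 0.632 / (1 - 0.368 R)};
#' result \code{(1 - w) err_bar + w err1'}.
#'
#' @param err_bar apparent error in \code{[0, 1]}.
#' @param err1 leave-one-out bootstrap error in \code{[0, 1]}.
#' @param gamma no-information rate in \code{[0, 1]}.
#' @return The B.632+ error estimate.
#' @export
b632plus_combine <- function(err_bar, err1, gamma) {
  stopifnot(err_bar >= 0, err_bar <= 1, err1 >= 0, err1 <= 1,
            gamma >= 0, gamma <= 1)
  err1p <- min(err1, gamma)
  r <- if (gamma > err_bar && err1p > err_bar) {
    (err1p - err_bar) / (gamma - err_bar)
  } else {
    0
  }
  r <- min(max(r, 0), 1)
  w <- 0.632 / (1 - 0.368 * r)
  (1 - w) * err_bar + w * err1p
}

# Resolve a selector argument to function(ds, G) -> ordered gene indices.
resolve_selector <- function(selector, spec, sd_denom = "n-1") {
  if (is.function(selector)) return(selector)
  selector <- match.arg(selector, c("kmgs", "kmsfs", "fisher"))
  switch(selector,
    kmgs = function(ds, G) kmgs_rank(ds, spec, sd_denom)$order[seq_len(G)],
    kmsfs = function(ds, G) kmsfs_select(ds, spec, G, sd_denom)$selected,
    fisher = function(ds, G) {
      sc <- fisher_scores(ds)
      order(-sc, seq_along(sc))[seq_len(G)]
    }
  )
}

# Linear SVM with a fixed contract: train on (X, y in {+1,-1}), predict labels.
fit_linear_svm <- function(X, y, C) {
  e1071::svm(x = X, y = factor(y, levels = c(-1L, 1L)),
             kernel = "linear", cost = C, scale = FALSE)
}

predict_svm <- function(model, X) {
  as.integer(as.character(predict(model, X)))
}

#' External B.632+ error curve
#'
#' Estimates the B.632+ classification error of a gene-selection pipeline as
#' a function of the number of selected DEGs, with selection performed
#' strictly inside each bootstrap training set ("external" selection): for
#' every bootstrap set, the selector sees only the in-bag samples, a linear
#' SVM is trained on the in-bag samples restricted to the top-g genes, and
#' errors are recorded on the out-of-bag samples. The leave-one-out
#' bootstrap error err1 averages each sample's out-of-bag misclassification
#' rate; the apparent error and no-information rate come from running the
#' full pipeline on the complete dataset.
#'
#' @param ds an [expression_dataset] (standardized for kernel selectors).
#' @param selector \code{"kmgs"}, \code{"kmsfs"}, \code{"fisher"}, or a
#'   function \code{f(ds, G)} returning at least G ordered gene indices.
#' @param spec a [kernel_spec()]; required for the kernel selectors.
#' @param svm_C regularization parameter of the linear SVM (default 1).
#' @param G number of gene counts to evaluate (curve runs over 1..G,
#'   default 100).
#' @param plan a [balanced_bootstrap()] plan for \code{nrow(ds$values)}
#'   samples.
#' @param sd_denom \code{"n-1"} (default) or \code{"n"}.
#' @return An object of class \code{error_curve}: list with
#'   \code{gene_counts}, \code{b632plus}, \code{err_bar}, \code{err1},
#'   \code{gamma} (each of length G), and \code{deg_sets}, the B + 1 gene
#'   lists selected in each bootstrap set and (last element) on the full
#'   data.
#' @export
external_b632plus_curve <- function(ds, selector, spec = NULL, svm_C = 1,
                                    G = 100L, plan, sd_denom = "n-1") {
  assert_two_class(ds)
  stopifnot(inherits(plan, "bootstrap_plan"))
  n <- nrow(ds$values)
  if (plan$n != n) kmg_stop("dim_mismatch", "plan was built for a different n")
  if (G > ncol(ds$values)) kmg_stop("bad_k", "G exceeds the number of genes")
  sel_fun <- resolve_selector(selector, spec, sd_denom)
  B <- plan$B

  err_counts <- matrix(0, n, G)   # out-of-bag misclassifications per sample
  oob_counts <- integer(n)        # times each sample was out-of-bag
  deg_sets <- vector("list", B + 1L)

  for (b in seq_len(B)) {
    inbag <- plan$sets[[b]]
    oob <- setdiff(seq_len(n), unique(inbag))
    ds_b <- subset_samples(ds, inbag)
    genes_b <- sel_fun(ds_b, G)[seq_len(G)]
    deg_sets[[b]] <- genes_b
    oob_counts[oob] <- oob_counts[oob] + 1L
    for (g in seq_len(G)) {
      cols <- genes_b[seq_len(g)]
      model <- tryCatch(
        fit_linear_svm(ds_b$values[, cols, drop = FALSE], ds_b$labels, svm_C),
        error = function(e) NULL)
      if (is.null(model)) {
        # degenerate in-bag set for this gene count: redraw a valid set
        warning(sprintf("SVM failed on bootstrap set %d; set redrawn", b),
                call. = FALSE)
        repeat {
          inbag2 <- sample(seq_len(n), n, replace = TRUE)
          if (length(unique(ds$labels[inbag2])) == 2L &&
              length(unique(inbag2)) < n) break
        }
        ds_b2 <- subset_samples(ds, inbag2)
        model <- fit_linear_svm(ds_b2$values[, cols, drop = FALSE],
                                ds_b2$labels, svm_C)
      }
      pred <- predict_svm(model, ds$values[oob, cols, drop = FALSE])
      wrong <- oob[pred != ds$labels[oob]]
      err_counts[wrong, g] <- err_counts[wrong, g] + 1L
    }
  }

  covered <- oob_counts > 0L
  err1 <- colMeans(err_counts[covered, , drop = FALSE] / oob_counts[covered])

  genes_full <- sel_fun(ds, G)[seq_len(G)]
  deg_sets[[B + 1L]] <- genes_full
  err_bar <- numeric(G)
  gamma <- numeric(G)
  b632 <- numeric(G)
  for (g in seq_len(G)) {
    cols <- genes_full[seq_len(g)]
    model <- fit_linear_svm(ds$values[, cols, drop = FALSE], ds$labels, svm_C)
    pred <- predict_svm(model, ds$values[, cols, drop = FALSE])
    err_bar[g] <- mean(pred != ds$labels)
    gamma[g] <- no_information_rate(ds$labels, pred)
    b632[g] <- b632plus_combine(err_bar[g], min(err1[g], 1), gamma[g])
  }

  structure(list(gene_counts = seq_len(G), b632plus = b632,
                 err_bar = err_bar, err1 = pmin(err1, 1), gamma = gamma,
                 deg_sets = deg_sets, svm_C = svm_C),
            class = "error_curve")
}

#' @export
print.error_curve <- function(x, ...) {
  g <- which.min(x$b632plus)
  cat(sprintf("error_curve over %d gene counts; min B.632+ = %.4f at %d gene(s)\n",
              length(x$gene_counts), x$b632plus[g], g))
  invisible(x)
}

#' @export
as.data.frame.error_curve <- function(x, ...) {
  data.frame(gene_count = x$gene_counts, b632plus = x$b632plus,
             err_bar = x$err_bar, err1 = x$err1, gamma = x$gamma)
}

#' Write an error curve as CSV
#'
#' @param curve an \code{error_curve}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_error_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
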