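# Independent, deliberately naive reference implementations used as oracles.
# These share no code with the package internals: everything is explicit
# loops and base-R arithmetic.

# sd with the same size-1 convention as the package, built on base sd().
oracle_sd <- function(v) if (length(v) < 2L) 0 else stats::sd(v)

# Two-pass z-score: rows first, then columns, sample (n-1) sd.
oracle_standardize <- function(x) {
  for (i in seq_len(nrow(x))) x[i, ] <- (x[i, ] - mean(x[i, ])) / stats::sd(x[i, ])
  for (j in seq_len(ncol(x))) x[, j] <- (x[, j] - mean(x[, j])) / stats::sd(x[, j])
  x
}

# Pairwise kernel evaluation, one entry at a time.
oracle_gram <- function(X, kind, sigma = NULL) {
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      K[i, j] <- if (kind == "linear") {
        sum(X[i, ] * X[j, ])
      } else {
        exp(-sum((X[i, ] - X[j, ])^2) / sigma)
      }
    }
  }
  K
}

oracle_normalize_columns <- function(K) {
  for (j in seq_len(ncol(K))) {
    d <- K[j, j]
    K[, j] <- if (d < 1e-12) 0 else K[, j] / d
  }
  K
}

# Separability of one column, straight from the definition.
oracle_column_sep <- function(column, self_index, labels) {
  same <- labels == labels[self_index]
  p_same <- column[same]
  p_opp <- column[!same]
  den <- oracle_sd(p_same) + oracle_sd(p_opp)
  if (den < 1e-12) return(0)
  (mean(p_same) - mean(p_opp)) / den
}

# Problem separability from raw data: build the kernel matrix entry by
# entry, normalize if linear, then score every column.
oracle_problem_sep <- function(X, labels, kind, sigma = NULL) {
  K <- oracle_gram(X, kind, sigma)
  if (kind == "linear") K <- oracle_normalize_columns(K)
  s <- vapply(seq_len(ncol(K)),
              function(j) oracle_column_sep(K[, j], j, labels), numeric(1))
  list(per_sample = s, total = sum(s))
}

# Naive KMSFS: rebuild the candidate Gram matrix from scratch (from the
# selected + candidate gene submatrix) at every step.
oracle_kmsfs <- function(X, labels, kind, sigma = NULL, T) {
  m <- ncol(X)
  selected <- integer(0)
  step_scores <- numeric(0)
  for (t in seq_len(T)) {
    best <- NA_integer_; best_score <- -Inf
    for (k in setdiff(seq_len(m), selected)) {
      tot <- oracle_problem_sep(X[, c(selected, k), drop = FALSE],
                                labels, kind, sigma)$total
      if (tot > best_score) { best_score <- tot; best <- k }
    }
    selected <- c(selected, best)
    step_scores <- c(step_scores, best_score)
  }
  list(selected = selected, step_scores = step_scores)
}

# Standard (non-nested) B.632+ on a fixed gene list: the reference the
# external estimator must reduce to when the selector ignores the data.
oracle_b632_fixed <- function(ds, genes, C, plan, G) {
  n <- nrow(ds$values)
  err_counts <- matrix(0, n, G)
  oob_counts <- integer(n)
  for (b in seq_len(plan$B)) {
    inbag <- plan$sets[[b]]
    oob <- setdiff(seq_len(n), unique(inbag))
    oob_counts[oob] <- oob_counts[oob] + 1L
    for (g in seq_len(G)) {
      cols <- genes[seq_len(g)]
      fit <- e1071::svm(x = ds$values[inbag, cols, drop = FALSE],
                        y = factor(ds$labels[inbag], levels = c(-1L, 1L)),
                        kernel = "linear", cost = C, scale = FALSE)
      pred <- as.integer(as.character(predict(fit, ds$values[oob, cols, drop = FALSE])))
      bad <- oob[pred != ds$labels[oob]]
      err_counts[bad, g] <- err_counts[bad, g] + 1L
    }
  }
  covered <- oob_counts > 0L
  out <- data.frame(err1 = numeric(G), err_bar = numeric(G),
                    gamma = numeric(G), b632 = numeric(G))
  for (g in seq_len(G)) {
    cols <- genes[seq_len(g)]
    fit <- e1071::svm(x = ds$values[, cols, drop = FALSE],
                      y = factor(ds$labels, levels = c(-1L, 1L)),
                      kernel = "linear", cost = C, scale = FALSE)
    pred <- as.integer(as.character(predict(fit, ds$values[, cols, drop = FALSE])))
    err_bar <- mean(pred != ds$labels)
    p <- sapply(c(-1L, 1L), function(k) mean(ds$labels == k))
    q <- sapply(c(-1L, 1L), function(k) mean(pred == k))
    gamma <- sum(p * (1 - q))
    err1 <- mean(err_counts[covered, g] / oob_counts[covered])
    err1p <- min(err1, gamma)
    r <- if (gamma > err_bar && err1p > err_bar) (err1p - err_bar) / (gamma - err_bar) else 0
    r <- min(max(r, 0), 1)
    w <- 0.632 / (1 - 0.368 * r)
    out[g, ] <- c(err1, err_bar, gamma, (1 - w) * err_bar + w * err1p)
  }
  out
}

# Small random two-class dataset (unstandardized unless asked).
random_dataset <- function(n = 8, m = 6, seed = 1, standardize = FALSE) {
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n * m), n, m)
    labels <- rep(c(1L, -1L), length.out = n)
    labels <- sample(labels)
    ds <- expression_dataset(x, labels)
    if (standardize) ds <- standardize_rows_then_columns(ds)
    ds
  })
}
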