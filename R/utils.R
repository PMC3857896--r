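# Internal helpers shared across modules.

# Signal a classed error so callers can distinguish failure modes
# (condition class "kmg_<subclass>").
kmg_stop <- function(subclass, msg) {
  cnd <- structure(
    class = c(paste0("kmg_", subclass), "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cnd)
}

# Sample standard deviation with a configurable denominator.
# A population of size 1 has sd 0 by convention (only reachable when a
# class has a single member).
kmg_sd <- function(x, denom = c("n-1", "n")) {
  denom <- match.arg(denom)
  n <- length(x)
  if (n <= 1L) return(0)
  v <- sum((x - mean(x))^2) / if (denom == "n-1") n - 1 else n
  sqrt(v)
}

# Column-wise means/sds of the same-class and opposite-class similarity
# populations for every column of an n x n similarity matrix, in one pass.
# `same` is the n x n logical matrix same[k, j] = labels[k] == labels[j]
# (self-similarity included in the same-class population).
sep_column_stats <- function(entries, same, denom = c("n-1", "n")) {
  denom <- match.arg(denom)
  n <- nrow(entries)
  n_same <- colSums(same)
  n_opp <- n - n_same
  sum_same <- colSums(entries * same)
  sum_all <- colSums(entries)
  sum_opp <- sum_all - sum_same
  sq <- entries^2
  ss_same <- colSums(sq * same)
  ss_opp <- colSums(sq) - ss_same

  mean_same <- sum_same / n_same
  mean_opp <- sum_opp / n_opp
  var_of <- function(ss, s, k) {
    d <- if (denom == "n-1") pmax(k - 1, 1) else k
    v <- (ss - s^2 / k) / d
    v[k <= 1] <- 0
    pmax(v, 0)
  }
  list(
    mean_same = mean_same, mean_opp = mean_opp,
    sd_same = sqrt(var_of(ss_same, sum_same, n_same)),
    sd_opp = sqrt(var_of(ss_opp, sum_opp, n_opp))
  )
}

# Per-sample separability scores for all columns of a similarity matrix.
# Returns list(per_sample, degenerate) where degenerate holds the indices
# of columns whose denominator fell below the hard guard.
sep_scores <- function(entries, labels, same = NULL, denom = "n-1") {
  if (is.null(same)) same <- outer(labels, labels, "==")
  st <- sep_column_stats(entries, same, denom)
  den <- st$sd_same + st$sd_opp
  degenerate <- which(den < 1e-12)
  s <- (st$mean_same - st$mean_opp) / den
  s[degenerate] <- 0
  list(per_sample = as.numeric(s), degenerate = degenerate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
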