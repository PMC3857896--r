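test_that("balanced bootstrap plans satisfy balance, coverage and class invariants", {
  labels <- rep(c(1L, -1L), 3)
  plan <- balanced_bootstrap(6, 3, labels, seed = 11)
  expect_length(plan$sets, 3)
  expect_true(all(lengths(plan$sets) == 6))
  counts <- tabulate(unlist(plan$sets), nbins = 6)
  expect_identical(counts, rep(3L, 6))
  for (s in plan$sets) {
    expect_lt(length(unique(s)), 6)                     # non-empty out-of-bag
    expect_identical(sort(unique(labels[s])), c(-1L, 1L)) # two-class in-bag
  }
})

test_that("bootstrap plans are deterministic in the seed", {
  labels <- rep(c(1L, -1L), 10)
  p1 <- balanced_bootstrap(20, 15, labels, seed = 5)
  p2 <- balanced_bootstrap(20, 15, labels, seed = 5)
  p3 <- balanced_bootstrap(20, 15, labels, seed = 6)
  expect_identical(p1$sets, p2$sets)
  expect_false(identical(p1$sets, p3$sets))
  counts3 <- tabulate(unlist(p3$sets), nbins = 20)
  expect_identical(counts3, rep(15L, 20))
})

test_that("unsatisfiable designs raise a named error", {
  # B = 1: the single balanced block is a permutation of all samples,
  # so the out-of-bag complement is always empty
  expect_error(balanced_bootstrap(4, 1, c(1L, -1L, -1L, -1L), seed = 1,
                                  max_attempts = 50),
               class = "kmg_unsatisfiable_plan")
})

test_that("the no-information rate follows the Efron-Tibshirani closed form", {
  expect_equal(no_information_rate(rep(c(1, -1), 4), rep(1, 8)), 0.5)
  expect_equal(no_information_rate(rep(c(1, -1), 4), rep(c(1, -1), 4)), 0.5)
  expect_equal(no_information_rate(c(1, 1, 1, -1), c(1, 1, 1, 1)), 0.25)
  expect_error(no_information_rate(numeric(0), numeric(0)), class = "kmg_bad_input")
})

test_that("the .632+ combination reproduces worked arithmetic cases", {
  expect_equal(b632plus_combine(0.2, 0.2, 0.5), 0.2)            # collapse to err_bar
  expect_equal(b632plus_combine(0, 0.5, 0.5), 0.5)              # R = 1, w = 1
  w <- 0.632 / (1 - 0.368 * 0.4)
  expect_equal(b632plus_combine(0, 0.2, 0.5), w * 0.2, tolerance = 1e-12)
  expect_equal(b632plus_combine(0, 0.2, 0.5), 0.14822, tolerance = 1e-4)
})

test_that("the .632+ combination is monotone in err1 and stays within its bounds", {
  grid <- seq(0, 1, by = 0.05)
  for (err_bar in c(0, 0.1, 0.3)) {
    for (gamma in c(0.25, 0.5, 0.9)) {
      vals <- vapply(grid, function(e1) b632plus_combine(err_bar, e1, gamma), numeric(1))
      expect_true(all(diff(vals) >= -1e-12))
      lo <- pmin(err_bar, pmin(grid, gamma))
      hi <- pmax(err_bar, pmin(grid, gamma))
      expect_true(all(vals >= lo - 1e-12 & vals <= hi + 1e-12))
    }
  }
})

test_that("the external estimator with a fixed selector equals the standalone oracle", {
  ds <- random_dataset(n = 20, m = 8, seed = 2, standardize = TRUE)
  plan <- balanced_bootstrap(20, 10, ds$labels, seed = 3)
  fixed_genes <- c(3L, 7L, 1L)
  fixed_selector <- function(ds, G) fixed_genes[seq_len(G)]
  curve <- external_b632plus_curve(ds, fixed_selector, G = 3, plan = plan)
  orc <- oracle_b632_fixed(ds, fixed_genes, C = 1, plan = plan, G = 3)
  expect_equal(curve$err1, orc$err1, tolerance = 1e-12)
  expect_equal(curve$err_bar, orc$err_bar, tolerance = 1e-12)
  expect_equal(curve$gamma, orc$gamma, tolerance = 1e-12)
  expect_equal(curve$b632plus, orc$b632, tolerance = 1e-12)
})

test_that("gene selection inside each bootstrap set sees in-bag samples only", {
  ds <- random_dataset(n = 16, m = 10, seed = 8, standardize = TRUE)
  plan <- balanced_bootstrap(16, 6, ds$labels, seed = 9)
  curve <- external_b632plus_curve(ds, "fisher", G = 4, plan = plan)
  # each recorded per-set selection must be re-derivable from in-bag data alone
  for (b in seq_len(plan$B)) {
    idx <- plan$sets[[b]]
    inbag <- expression_dataset(ds$values[idx, , drop = FALSE], ds$labels[idx])
    sc <- fisher_scores(inbag)
    expect_identical(curve$deg_sets[[b]], order(-sc, seq_along(sc))[1:4])
  }
  # the full-set selection is the last element
  sc_full <- fisher_scores(ds)
  expect_identical(curve$deg_sets[[plan$B + 1]], order(-sc_full, seq_along(sc_full))[1:4])

  # relabeling changes the out-of-bag error but the curve stays a valid contract
  ds_perm <- expression_dataset(ds$values, withr::with_seed(1, sample(ds$labels)),
                                ds$gene_ids, ds$sample_ids)
  curve_perm <- external_b632plus_curve(ds_perm, "fisher", G = 4, plan = plan)
  expect_false(isTRUE(all.equal(curve$err1, curve_perm$err1)))
})

test_that("error-curve components respect the estimator's invariants", {
  sim <- generate_dataset(n_pos = 10, n_neg = 10, m = 30, n_linear_deg = 2,
                          delta = 2, seed = 4)
  plan <- balanced_bootstrap(20, 12, sim$dataset$labels, seed = 5)
  curve <- external_b632plus_curve(sim$dataset, "kmgs", spec = kernel_spec("linear"),
                                   G = 5, plan = plan)
  for (v in list(curve$b632plus, curve$err_bar, curve$err1, curve$gamma)) {
    expect_true(all(v >= 0 & v <= 1))
  }
  err1p <- pmin(curve$err1, curve$gamma)
  expect_true(all(curve$b632plus >= pmin(curve$err_bar, err1p) - 1e-12))
  expect_true(all(curve$b632plus <= pmax(curve$err_bar, err1p) + 1e-12))
})

test_that("err1 of a majority-class rule approaches the out-of-bag minority fraction", {
  n <- 40
  labels <- rep(c(1L, -1L), c(24, 16))   # minority fraction 0.4
  plan <- balanced_bootstrap(n, 200, labels, seed = 17)
  err_counts <- numeric(n); oob_counts <- integer(n)
  for (s in plan$sets) {
    oob <- setdiff(seq_len(n), unique(s))
    majority <- if (sum(labels[s] == 1L) >= sum(labels[s] == -1L)) 1L else -1L
    oob_counts[oob] <- oob_counts[oob] + 1L
    wrong <- oob[labels[oob] != majority]
    err_counts[wrong] <- err_counts[wrong] + 1
  }
  err1 <- mean((err_counts / oob_counts)[oob_counts > 0])
  expect_lt(abs(err1 - 0.4), 0.05)
})
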