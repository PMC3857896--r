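test_that("delimited loading recodes labels first-seen-positive and validates shape", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,g1,g2,label",
               "s1,1.0,2.0,A",
               "s2,1.5,2.5,A",
               "s3,3.0,4.0,B"), f)
  ds <- load_expression_matrix(f, label_source = "label")
  expect_s3_class(ds, "expression_dataset")
  expect_identical(ds$labels, c(1L, 1L, -1L))
  expect_equal(dim(ds$values), c(3L, 2L))
  expect_identical(ds$gene_ids, c("g1", "g2"))
})

test_that("loader raises distinct named errors for bad inputs", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,g1,g2,label",
               "s1,1.0,oops,A",
               "s2,1.5,2.5,B"), f)
  err <- tryCatch(load_expression_matrix(f, label_source = "label"),
                  condition = function(c) c)
  expect_s3_class(err, "kmg_parse_error")
  expect_match(conditionMessage(err), "s1")
  expect_match(conditionMessage(err), "g2")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,g1,label", "s1,1,A", "s2,2,B", "s3,3,C"), f2)
  expect_error(load_expression_matrix(f2, label_source = "label"),
               class = "kmg_label_classes")

  expect_error(
    expression_dataset(matrix(1:6, 3, 2), c(1L, -1L)),
    class = "kmg_dim_mismatch")
})

test_that("genes-in-rows orientation and side-file labels are honored", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2\ts3",
               "g1\t1\t2\t3",
               "g2\t4\t5\t6",
               "label\t0\t0\t1"), f)
  ds <- load_expression_matrix(f, orientation = "genes_in_rows",
                               label_source = "label", delimiter = "\t")
  expect_equal(dim(ds$values), c(3L, 2L))
  expect_identical(ds$labels, c(1L, 1L, -1L))
  expect_equal(ds$values[, "g2"], c(s1 = 4, s2 = 5, s3 = 6))
})

test_that("MATLAB archives round-trip through the scipy-based reader", {
  mat <- withr::local_tempfile(fileext = ".mat")
  code <- paste(
    "import numpy as np, scipy.io",
    "rng = np.random.default_rng(7)",
    "X = rng.normal(size=(6, 9))",
    "y = np.array([1, 1, 1, -1, -1, -1])",
    sprintf("scipy.io.savemat(r'%s', {'expr': X, 'labels': y})", mat),
    sep = "\n")
  status <- system2("python", c("-c", shQuote(code)))
  expect_identical(status, 0L)
  ds <- load_expression_matrix(mat)
  expect_equal(dim(ds$values), c(6L, 9L))
  expect_identical(ds$labels, c(1L, 1L, 1L, -1L, -1L, -1L))
})

test_that("two-pass standardization matches the independent oracle and fixes columns", {
  x <- matrix(c(1, 5, 2, 2, 3, 9, 7, 4, 6), 3, 3)
  ds <- expression_dataset(x, c(1L, 1L, -1L))
  out <- standardize_rows_then_columns(ds)
  expect_equal(out$values, oracle_standardize(x), tolerance = 1e-12,
               ignore_attr = TRUE)

  big <- random_dataset(n = 10, m = 7, seed = 3)
  std <- standardize_rows_then_columns(big)
  expect_true(all(abs(colMeans(std$values)) < 1e-9))
  expect_true(all(abs(apply(std$values, 2, sd) - 1) < 1e-9))
})

test_that("standardization reports the offending zero-variance index", {
  x <- matrix(c(1, 1, 1, 2, 3, 4), 3, 2)
  x[2, ] <- c(5, 5)  # constant row 2
  err <- tryCatch(standardize_rows_then_columns(expression_dataset(x, c(1L, 1L, -1L))),
                  condition = function(c) c)
  expect_s3_class(err, "kmg_zero_variance")
  expect_match(conditionMessage(err), "row")
  expect_match(conditionMessage(err), "2")

  # identical rows leave every gene column constant after the row pass
  y <- matrix(rep(c(1, 2, 3), 3), 3, 3, byrow = TRUE)
  err2 <- tryCatch(standardize_rows_then_columns(expression_dataset(y, c(1L, 1L, -1L))),
                   condition = function(c) c)
  expect_s3_class(err2, "kmg_zero_variance")
  expect_match(conditionMessage(err2), "column")

  # a 2 x 2 matrix always degenerates: both rows z-score to the same pair
  expect_error(
    standardize_rows_then_columns(expression_dataset(matrix(c(1, 3, 2, 4), 2, 2),
                                                     c(1L, -1L))),
    class = "kmg_zero_variance")
})

test_that("thresholding/filtering/log10 preprocessing matches per-gene arithmetic", {
  # 3 samples x 4 genes; genes 2 and 3 violate the filters
  vals <- rbind(c(120, 50,  700, 200),
                c(900, 200, 1000, 4000),
                c(150, 80,  650, 900))
  ds <- expression_dataset(vals, c(1L, 1L, -1L),
                           gene_ids = c("a", "b", "c", "d"))
  out <- dudoit_preprocess(ds)
  # oracle: clamp each gene, test both filters, log10 survivors
  clamped <- pmin(pmax(vals, 100), 16000)
  keep <- logical(4)
  for (j in 1:4) {
    g <- clamped[, j]
    keep[j] <- (max(g) / min(g) > 5) && (max(g) - min(g) > 500)
  }
  expect_identical(out$gene_ids, c("a", "b", "c", "d")[keep])
  expect_equal(ncol(out$values), 2L)
  expect_equal(out$values, log10(clamped[, keep]), ignore_attr = TRUE)
})

test_that("a low-ratio gene is clamped then removed", {
  vals <- cbind(c(50, 200), c(100, 5000))
  ds <- expression_dataset(vals, c(1L, -1L), gene_ids = c("low", "ok"))
  out <- dudoit_preprocess(ds)
  expect_identical(out$gene_ids, "ok")
})

test_that("the gene filter is idempotent on its own output", {
  ds <- expression_dataset(matrix(runif(60, 50, 20000), 5, 12), rep(c(1L, -1L), c(2, 3)))
  once <- dudoit_preprocess(ds)
  # re-applying the filter predicate to surviving (pre-log) genes removes nothing
  clamped <- pmin(pmax(ds$values, 100), 16000)
  mx <- apply(clamped, 2, max); mn <- apply(clamped, 2, min)
  keep <- mx / mn > 5 & mx - mn > 500
  again <- keep[keep]
  expect_true(all(again))
  expect_equal(sum(keep), ncol(once$values))
})

test_that("Fisher prescreen keeps top-k genes in original order with stated tie rule", {
  ds <- random_dataset(n = 12, m = 9, seed = 5)
  expect_identical(fisher_prescreen(ds, 9)$gene_ids, ds$gene_ids)

  # gene 2 engineered to dominate
  x <- cbind(rnorm(8, 0, 1), c(rep(4, 4), rep(-4, 4)) + rnorm(8, 0, 0.1), rnorm(8, 0, 1))
  ds2 <- expression_dataset(x, rep(c(1L, -1L), each = 4), gene_ids = c("g1", "g2", "g3"))
  sc <- fisher_scores(ds2)
  expect_identical(which.max(sc), 2L)
  expect_identical(fisher_prescreen(ds2, 1)$gene_ids, "g2")

  # exactly tied scores: lower index retained
  xx <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  ds3 <- expression_dataset(xx, c(1L, 1L, -1L, -1L), gene_ids = c("first", "second"))
  expect_identical(fisher_prescreen(ds3, 1)$gene_ids, "first")

  expect_error(fisher_prescreen(ds, 10), class = "kmg_bad_k")
})

test_that("prescreen gene sets are nested in k", {
  ds <- random_dataset(n = 10, m = 15, seed = 11)
  for (k1 in c(2, 5, 9)) {
    for (k2 in c(10, 14)) {
      g1 <- fisher_prescreen(ds, k1)$gene_ids
      g2 <- fisher_prescreen(ds, k2)$gene_ids
      expect_true(all(g1 %in% g2))
    }
  }
})
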