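test_that("reading marks NA/empty cells as missing and validates shape", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,G1,G2",
               "A,1.5,NA",
               "B,2.0,3.5",
               "C,0.25,-1"), f)
  x <- read_expression(f)
  expect_equal(dim(x), c(3L, 2L))
  expect_equal(sum(missing_mask(x)), 1L)
  expect_true(missing_mask(x)["A", "G2"])
  expect_equal(x$values["C", "G1"], 0.25)

  # ragged row: header announces 2 genes, row B carries only one value
  g <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,G1,G2", "A,1,2", "B,1"), g)
  expect_error(read_expression(g), "ragged")

  # duplicate sample IDs rejected
  h <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,G1", "A,1", "A,2"), h)
  expect_error(read_expression(h), "duplicate sample")
})

test_that("write/read round-trips values and mask bit-exactly", {
  set.seed(41)
  for (rep in 1:3) {
    v <- matrix(rnorm(5 * 4) * 10^sample(-3:3, 20, TRUE), 5, 4)
    v[sample(20, 4)] <- NA
    x <- expression_matrix(v)
    f <- tempfile(fileext = ".csv")
    write_expression(x, f)
    x2 <- read_expression(f)
    expect_identical(x2$values, x$values)
    expect_identical(missing_mask(x2), missing_mask(x))
  }
})

test_that("label files round-trip and keep class order of first appearance", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,label", "A,lumA", "B,basal", "C,lumA"), f)
  y <- read_labels(f)
  expect_equal(levels(y), c("lumA", "basal"))
  expect_equal(as.character(y), c("lumA", "basal", "lumA"))
  expect_equal(names(y), c("A", "B", "C"))
  expect_error(read_labels(f, levels = c("lumA")), "outside the class list")
})

test_that("missing-sample filter removes strictly above the threshold", {
  v <- matrix(1, 3, 5,
              dimnames = list(c("keep", "edge", "drop"), paste0("G", 1:5)))
  v["drop", 1:2] <- NA   # 40% missing
  v["edge", 1] <- NA     # exactly 20% missing: retained
  r <- filter_missing_samples(expression_matrix(v), threshold = 0.20)
  expect_equal(r$removed, "drop")
  expect_equal(rownames(r$x$values), c("keep", "edge"))

  # no missing values: identity, empty removed list
  clean <- expression_matrix(matrix(rnorm(10), 2, 5))
  r2 <- filter_missing_samples(clean)
  expect_identical(r2$x$values, clean$values)
  expect_length(r2$removed, 0)

  # everything removed is an error, not an empty matrix
  allna <- matrix(NA_real_, 2, 4)
  allna[, 1] <- 1
  expect_error(filter_missing_samples(expression_matrix(allna)),
               "relaxing")
})

test_that("knn imputation matches a brute-force neighbor ranking", {
  # k = 1: nearest-neighbor copy from an identical-elsewhere sample
  v <- rbind(A = c(1, 2, NA, 4), B = c(1, 2, 9, 4), C = c(50, 60, 70, 80))
  colnames(v) <- paste0("G", 1:4)
  xi <- knn_impute(expression_matrix(v), k = 1)
  expect_equal(xi$values["A", "G3"], 9)

  # no missing values: identity
  clean <- expression_matrix(matrix(rnorm(12), 3, 4))
  expect_identical(knn_impute(clean, 2)$values, clean$values)

  # 6 x 4 fixture vs the exhaustive oracle, k = 3; observed cells untouched
  set.seed(7)
  w <- matrix(rnorm(24), 6, 4, dimnames = list(paste0("S", 1:6),
                                               paste0("G", 1:4)))
  w[cbind(c(1, 2, 4, 6), c(2, 3, 1, 4))] <- NA
  got <- knn_impute(expression_matrix(w), k = 3)$values
  want <- brute_impute(w, k = 3)
  expect_equal(got, want, tolerance = 1e-12)
  expect_identical(got[!is.na(w)], w[!is.na(w)])

  # a gene observed nowhere cannot be imputed
  bad <- matrix(c(1, 2, NA, NA), 2, 2)
  expect_error(knn_impute(expression_matrix(bad), 1), "missing in every")
})

test_that("standardization follows the z-score contract", {
  # constant column maps to zeros
  v <- cbind(G1 = c(5, 5, 5), G2 = c(1, 2, 3))
  rownames(v) <- paste0("S", 1:3)
  r <- zscore_normalize(expression_matrix(v))
  expect_equal(unname(r$x$values[, "G1"]), c(0, 0, 0))
  # population sd: mean 2, variance 2/3
  expect_equal(unname(r$x$values[, "G2"]),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(r$stats$spread[2], sqrt(2 / 3))

  # literal variance-division variant
  rv <- zscore_normalize(expression_matrix(v), divisor = "var")
  expect_equal(unname(rv$x$values[, "G2"]), c(-1.5, 0, 1.5))

  # already standardized column is a fixed point
  z <- cbind(G1 = c(-1, 0, 1) / sqrt(2 / 3))
  rownames(z) <- paste0("S", 1:3)
  r2 <- zscore_normalize(expression_matrix(z))
  expect_equal(r2$x$values, expression_matrix(z)$values, tolerance = 1e-12)

  # missing values are a precondition error
  nav <- matrix(c(1, NA, 3, 4), 2, 2)
  expect_error(zscore_normalize(expression_matrix(nav)), "impute")
})

test_that("filter-impute-normalize chain is deterministic and centers genes", {
  d <- make_dataset(synthetic_spec(n_per_class = c(15, 15), n_genes = 12,
                                   n_informative = 4, shift = 2,
                                   missing_rate = 0.1, seed = 99))
  chain <- function() {
    f <- filter_missing_samples(d$x, 0.5)
    zscore_normalize(knn_impute(f$x, 3))$x$values
  }
  a <- chain()
  b <- chain()
  expect_identical(a, b)
  expect_true(all(abs(colMeans(a)) < 1e-9))
  sds <- sqrt(colMeans(sweep(a, 2, colMeans(a))^2))
  expect_true(all(sds == 0 | abs(sds - 1) < 1e-9))
})

test_that("normalization stats transfer to held-out samples without refitting", {
  set.seed(3)
  tr <- expression_matrix(matrix(rnorm(40, mean = 5), 10, 4))
  te <- expression_matrix(matrix(rnorm(8, mean = 5), 2, 4))
  r <- zscore_normalize(tr)
  out <- apply_normalization(te, r$stats)
  manual <- sweep(sweep(te$values, 2, r$stats$mean), 2, r$stats$spread, "/")
  expect_equal(out$values, manual)
})
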