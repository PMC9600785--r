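test_that("sample matrices load from delimited text with strict validation", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "3,4", "5,6", "7,8"), f)
  x <- load_sample_matrix(f)
  expect_identical(dim(x), c(4L, 2L))
  expect_identical(colnames(x), c("a", "b"))
  expect_equal(x[, "a"], c(1, 3, 5, 7))

  writeLines(c("a,b", "1,2", "3,NA"), f)
  expect_error(load_sample_matrix(f), "row 2, column 'b'")
  writeLines(c("a,b", "1,2,3"), f)
  expect_error(load_sample_matrix(f), "3 fields, expected 2")
  writeLines(c("a,a", "1,2"), f)
  expect_error(load_sample_matrix(f), "duplicated")
  expect_error(load_sample_matrix(tempfile()), "not found")
})

test_that("sample matrix write/load round-trips are lossless", {
  f <- withr::local_tempfile(fileext = ".csv")
  set.seed(42)
  for (rep in 1:5) {
    x <- rand_sample_matrix(sample(2:30, 1), sample(1:12, 1))
    x <- x * 10^sample(-8:8, ncol(x), replace = TRUE)
    write_sample_matrix(x, f)
    expect_identical(load_sample_matrix(f), x)
  }
  # TSV dialect
  write_sample_matrix(x, f, delimiter = "\t")
  expect_identical(load_sample_matrix(f, delimiter = "\t"), x)
})

test_that("z-score normalization uses the population sd and is idempotent", {
  x <- cbind(a = c(1, 2, 3), b = c(2, 4, 8))
  z <- zscore_normalize(x)
  expect_equal(z[, "a"], c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(colMeans(z), c(a = 0, b = 0), tolerance = 1e-10)
  expect_equal(colMeans(z^2), c(a = 1, b = 1), tolerance = 1e-10)
  expect_equal(zscore_normalize(z), z, tolerance = 1e-10)
  expect_error(zscore_normalize(cbind(a = c(5, 5, 5), b = 1:3)),
               "constant column.*a")
})

test_that("min-max normalization maps columns onto [0,1] preserving order", {
  x <- cbind(a = c(2, 4, 6), b = c(0, 0.5, 1))
  m <- minmax_normalize(x)
  expect_equal(m[, "a"], c(0, 0.5, 1))
  expect_equal(m[, "b"], x[, "b"])          # already spanning [0, 1]
  expect_equal(minmax_normalize(m), m, tolerance = 1e-10)
  set.seed(7)
  r <- rand_sample_matrix(50, 3)
  mr <- minmax_normalize(r)
  expect_equal(unname(apply(mr, 2, min)), c(0, 0, 0))
  expect_equal(unname(apply(mr, 2, max)), c(1, 1, 1))
  for (j in 1:3) expect_identical(order(mr[, j]), order(r[, j]))
  expect_error(minmax_normalize(cbind(a = c(1, 1), b = c(1, 2))),
               "constant column.*a")
})

test_that("absolute-row-sum filter keeps the smallest rows in order", {
  x <- rbind(c(2, 3), c(0.5, 0.5), c(1, 2))
  colnames(x) <- c("a", "b")
  kept <- filter_outliers_by_abs_sum(x, 2)
  expect_equal(unname(rowSums(abs(kept))), c(1, 3))   # original order kept
  expect_identical(filter_outliers_by_abs_sum(x, 3), x)
  expect_error(filter_outliers_by_abs_sum(x, 4), "exceeds")
  expect_error(filter_outliers_by_abs_sum(x, 0), "positive")

  set.seed(11)
  big <- rand_sample_matrix(500, 4)
  f <- filter_outliers_by_abs_sum(big, 300)
  kept_sums <- rowSums(abs(f))
  all_sums <- rowSums(abs(big))
  dropped <- sort(all_sums, decreasing = TRUE)[1:200]
  expect_lte(max(kept_sums), min(dropped))
  # permutation invariance of the retained multiset (distinct sums a.s.)
  perm <- sample(nrow(big))
  f2 <- filter_outliers_by_abs_sum(big[perm, ], 300)
  expect_equal(sort(rowSums(abs(f2))), sort(kept_sums))
})

test_that("adjacency serialization round-trips and edge lists are ordered", {
  g <- mk_adj(2, list(c("a", "b")), var_names = c("a", "b"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_adjacency(g, f, format = "edge-list")
  expect_identical(readLines(f), "a\tb\t1")
  write_adjacency(mk_adj(3), f, format = "edge-list")
  expect_identical(readLines(f), character(0))

  set.seed(3)
  w <- matrix(rnorm(16), 4, 4, dimnames = list(paste0("x", 1:4),
                                               paste0("x", 1:4)))
  diag(w) <- 0
  fc <- withr::local_tempfile(fileext = ".csv")
  write_adjacency(w, fc, format = "matrix-csv")
  expect_equal(read_adjacency(fc), w)

  write_adjacency(w, f, format = "edge-list")
  lines <- read.table(f, sep = "\t")
  src_idx <- match(lines$V1, paste0("x", 1:4))
  expect_false(is.unsorted(src_idx))
})
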