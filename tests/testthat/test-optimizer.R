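test_that("acyclicity term is zero on DAGs and matches closed forms", {
  w0 <- matrix(0, 3, 3)
  a <- acyclicity_term(w0)
  expect_equal(a$value, 0)
  expect_equal(a$gradient, w0)

  w2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(acyclicity_term(w2)$value, 2 * cosh(1) - 2, tolerance = 1e-12)

  set.seed(2)
  wu <- matrix(rnorm(25), 5, 5)
  wu[lower.tri(wu, diag = TRUE)] <- 0
  expect_lt(abs(acyclicity_term(wu)$value), 1e-10)
})

test_that("acyclicity term separates DAGs from cyclic supports (all 3-node digraphs)", {
  off <- which(!diag(3))
  for (code in 0:63) {
    w <- matrix(0, 3, 3)
    w[off] <- as.integer(intToBits(code))[1:6]
    h <- acyclicity_term(w)$value
    if (has_cycle_dfs(w)) {
      expect_gt(h, 0.5)
    } else {
      expect_lt(abs(h), 1e-10)
    }
  }
})

test_that("SEM loss matches direct arithmetic and exact-fit cases", {
  set.seed(4)
  x <- rand_sample_matrix(20, 3)
  w0 <- matrix(0, 3, 3)
  expect_equal(sem_loss(x, w0, lambda = 0)$value, sum(x^2) / (2 * nrow(x)))

  # exact fit of column 2 leaves only column 1's residual
  x1 <- rnorm(100)
  xx <- cbind(a = x1, b = 2 * x1)
  w <- matrix(c(0, 0, 2, 0), 2, 2)
  expect_equal(sem_loss(xx, w, lambda = 0)$value, sum(x1^2) / 200)

  # fixed instance vs direct matrix arithmetic
  xf <- cbind(a = c(1, 0, 1), b = c(0, 1, 1))
  wf <- matrix(c(0, 0, 0.5, 0), 2, 2)
  r <- xf %*% wf - xf
  expect_equal(sem_loss(xf, wf, lambda = 0.1)$value,
               sum(r^2) / 6 + 0.1 * 0.25)
  gr_direct <- crossprod(xf, r) / 3 + 0.2 * wf
  diag(gr_direct) <- 0
  expect_equal(sem_loss(xf, wf, lambda = 0.1)$gradient, gr_direct)
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(6)
  for (d in c(2, 4, 5)) {
    w <- matrix(rnorm(d * d, sd = 0.6), d, d)
    x <- rand_sample_matrix(30, d)
    gb <- rand_digraph(d, 0.5)

    fd <- fd_gradient(function(m) acyclicity_term(m)$value, w)
    an <- acyclicity_term(w)$gradient
    expect_equal(an, fd, tolerance = 1e-4)

    fd <- fd_gradient(function(m) sem_loss(x, m, lambda = 0.1)$value, w)
    an <- sem_loss(x, w, lambda = 0.1)$gradient
    off <- !diag(d)  # gradient diagonal is pinned to zero by contract
    expect_equal(an[off], fd[off], tolerance = 1e-4)

    fd <- fd_gradient(function(m) direction_penalty(m, gb)$value, w)
    an <- direction_penalty(w, gb)$gradient
    expect_lt(max(abs(an - fd)), 1e-6)
  }
})

test_that("direction penalty evaluates the masked Frobenius norm", {
  g <- mk_adj(2, list(c("x1", "x2")))
  gb <- complement_matrix(g)
  w <- matrix(0, 2, 2)
  w[1, 2] <- 0.7                          # supported where G permits
  expect_equal(direction_penalty(w, gb)$value, 0)
  w2 <- matrix(0, 2, 2)
  w2[2, 1] <- 0.5                         # forbidden direction
  dp <- direction_penalty(w2, gb)
  expect_equal(dp$value, 0.25)
  expect_equal(dp$gradient[2, 1], 1.0)
})

test_that("thresholding is strict and monotone in epsilon", {
  expect_equal(sum(threshold_weights(matrix(0, 3, 3), 0.2)), 0)
  w <- matrix(0, 2, 2)
  w[1, 2] <- 0.21
  w[2, 1] <- 0.19
  g <- threshold_weights(w, 0.2)
  expect_equal(g[1, 2], 1)
  expect_equal(g[2, 1], 0)
  set.seed(8)
  wr <- matrix(rnorm(36), 6, 6)
  diag(wr) <- 0
  for (rep in 1:10) {
    e1 <- runif(1, 0.05, 1)
    e2 <- e1 + runif(1, 0, 1)
    expect_true(all(threshold_weights(wr, e2) <= threshold_weights(wr, e1)))
  }
})

test_that("structure optimization recovers simple planted mechanisms", {
  # d = 1: no admissible edges
  x1 <- matrix(rnorm(50), dimnames = list(NULL, "a"))
  expect_equal(unclass(optimize_structure(x1, matrix(0, 1, 1)))[1, 1], 0)

  # d = 2: x2 = 0.8 x1 + noise, direction supplied
  set.seed(14)
  a <- rnorm(1000)
  x <- cbind(x1 = a, x2 = 0.8 * a + rnorm(1000, sd = 0.1))
  g <- mk_adj(2, list(c("x1", "x2")))
  w <- suppressWarnings(optimize_structure(zscore_normalize(x), g))
  bin <- threshold_weights(w, 0.2)
  expect_equal(bin, mk_adj(2, list(c("x1", "x2"))))

  # determinism and row-permutation invariance
  w2 <- suppressWarnings(optimize_structure(zscore_normalize(x), g))
  expect_identical(unclass(w), unclass(w2))
  perm <- sample(nrow(x))
  w3 <- suppressWarnings(optimize_structure(zscore_normalize(x[perm, ]), g))
  expect_equal(unclass(w), unclass(w3), tolerance = 1e-8)
})

test_that("converged runs yield feasible thresholded graphs", {
  set.seed(15)
  a <- rnorm(800)
  x <- cbind(x1 = a, x2 = a + rnorm(800), x3 = rnorm(800))
  g <- causal_direction_matrix(x)
  w <- suppressWarnings(optimize_structure(zscore_normalize(x), g))
  bin <- threshold_weights(w, 0.2)
  expect_false(has_cycle_dfs(bin))
  expect_equal(sum(bin * complement_matrix(g)), 0)
  tr <- attr(w, "trace")
  # constraint violations shrink as the multipliers grow
  expect_lt(tr$h[nrow(tr)], tr$h[1] + 1e-12)
  expect_lt(tr$g[nrow(tr)], tr$g[1] + 1e-12)
})
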