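test_that("circular splits enumerate the arcs of the ordering once each", {
  sp <- circular_splits(c(1L, 2L, 3L, 4L))
  expect_length(sp, 6)
  keys <- sort(split_keys(sp))
  # 4 trivial splits plus {1,2}|{3,4} and {1,4}|{2,3}, canonical sides
  # excluding taxon 1
  expect_equal(keys, sort(c("2", "3", "4", "2,3,4", "3,4", "2,3")))
  expect_length(circular_splits(1:5), 10)
  expect_equal(sum(vapply(circular_splits(1:5), is_trivial_split,
                          logical(1), n = 5)), 5)
})

test_that("rotations and reversals induce the same split set", {
  sigma <- c(2L, 5L, 1L, 4L, 3L, 6L)
  base <- sort(split_keys(circular_splits(sigma)))
  expect_equal(sort(split_keys(circular_splits(c(sigma[3:6], sigma[1:2])))),
               base)
  expect_equal(sort(split_keys(circular_splits(rev(sigma)))), base)
})

test_that("the design matrix marks separated pairs and has full rank", {
  # trivial split {3}: pair (1,2) not separated, pair (1,3) separated
  A1 <- split_design_matrix(list(3L), 4)
  expect_equal(dim(A1), c(6L, 1L))
  expect_equal(unname(A1["1,2", 1]), 0)
  expect_equal(unname(A1["1,3", 1]), 1)

  sp <- circular_splits(c(1L, 2L, 3L, 4L))
  A <- split_design_matrix(sp, 4)
  expect_equal(dim(A), c(6L, 6L))
  expect_equal(qr(A)$rank, 6L)
  expect_true(all(A %in% c(0, 1)))

  # each trivial-split column has exactly n - 1 ones
  triv <- vapply(sp, is_trivial_split, logical(1), n = 4)
  expect_true(all(colSums(A[, triv]) == 3))
})

test_that("OLS solves the quartet system exactly and matches the closed form", {
  d <- quartet_tree_metric()
  sigma <- 1:4
  sys <- weight_splits(d, sigma, method = "ols")
  keys <- split_keys(sys$splits)
  expected <- c("2" = 1, "3" = 1, "4" = 1, "2,3,4" = 1, "3,4" = 1, "2,3" = 0)
  expect_equal(sys$weights, unname(expected[keys]), tolerance = 1e-10)
  expect_equal(fit_norm(sys), 0, tolerance = 1e-10)

  # closed form b = (A'A)^-1 A'd on a full-rank system
  b_closed <- solve(crossprod(sys$design),
                    crossprod(sys$design, sys$dvec))
  expect_equal(as.numeric(b_closed), sys$weights, tolerance = 1e-9)
})

test_that("OLS recovers arbitrary non-negative weights from consistent data", {
  for (s in 1:5) {
    sp <- circular_splits(withr::with_seed(s, sample.int(6)))
    A <- split_design_matrix(sp, 6)
    w <- withr::with_seed(s, stats::runif(ncol(A)))
    b <- fit_ols(A, as.numeric(A %*% w))
    expect_equal(b, w, tolerance = 1e-9)
  }
})

test_that("NNLS matches OLS when OLS is feasible, and satisfies KKT", {
  d <- quartet_tree_metric()
  sys_nn <- weight_splits(d, 1:4, method = "nnls")
  sys_ols <- weight_splits(d, 1:4, method = "ols")
  expect_equal(sys_nn$weights, sys_ols$weights, tolerance = 1e-9)
  expect_equal(fit_norm(sys_nn), 0, tolerance = 1e-9)
  expect_equal(sum(sys_nn$weights > 1e-10), 5L)
  expect_kkt(sys_nn$design, sys_nn$dvec, sys_nn$weights)
})

test_that("NNLS zeroes the split OLS drives negative; exhaustive oracle agrees", {
  d <- unclass(quartet_tree_metric())
  # inflate one within-cherry distance so the unconstrained fit must go
  # negative somewhere
  d[1, 2] <- d[2, 1] <- 4.5
  dd <- distance_matrix(d)
  sp <- circular_splits(1:4)
  A <- split_design_matrix(sp, 4)
  dv <- dd[cbind(c(1,1,1,2,2,3), c(2,3,4,3,4,4))]
  b_ols <- fit_ols(A, dv)
  expect_true(any(b_ols < -1e-8))
  b_nn <- fit_nnls(A, dv)
  expect_true(all(b_nn >= 0))
  expect_equal(b_nn[which(b_ols < -1e-8)], rep(0, sum(b_ols < -1e-8)))
  r_ols <- sqrt(sum((A %*% b_ols - dv)^2))
  r_nn <- sqrt(sum((A %*% b_nn - dv)^2))
  expect_gte(r_nn, r_ols)
  oracle <- nnls_exhaustive(A, dv)
  expect_equal(b_nn, oracle$w, tolerance = 1e-8)
  expect_equal(r_nn, oracle$resid, tolerance = 1e-8)
  expect_kkt(A, dv, b_nn)
})

test_that("NNLS recovers generating weights of circular metrics at their cycle", {
  for (s in 1:5) {
    k <- random_circular_metric(7, seed = 500 + s)
    sys <- weight_splits(k$d, k$cycle, method = "nnls")
    m <- match(split_keys(k$splits), split_keys(sys$splits))
    expect_false(anyNA(m))
    expect_equal(sys$weights[m], k$weights, tolerance = 1e-8)
    expect_lt(fit_norm(sys), 1e-8)
    expect_kkt(sys$design, sys$dvec, sys$weights)
  }
})

test_that("filtering drops only (near-)zero weights", {
  d <- quartet_tree_metric()
  sys <- weight_splits(d, 1:4)
  filt <- filter_splits(sys)
  expect_length(filt$splits, 5)        # 2n - 3 for the quartet tree
  expect_true(all(filt$weights > 1e-10))
  expect_equal(ncol(filt$design), 5L)
  # threshold above the max weight empties the system
  expect_length(filter_splits(sys, max(sys$weights) + 1)$splits, 0)
  # all weights above threshold: identity
  expect_identical(filter_splits(filt, 1e-10), filt)
})

test_that("fit norm is the Euclidean residual and ordered OLS <= NNLS", {
  d <- quartet_tree_metric()
  sys <- weight_splits(d, 1:4)
  expect_equal(fit_norm(sys), 0, tolerance = 1e-9)
  zero <- sys; zero$weights <- rep(0, length(zero$weights))
  expect_equal(fit_norm(zero), sqrt(sum(sys$dvec^2)))
  for (s in 1:10) {
    g <- random_tree_metric(6, seed = 600 + s)
    dp <- perturb_distances(g$d, 0.1, seed = s)
    nn <- weight_splits(dp, initial_ordering(dp), method = "nnls")
    ol <- weight_splits(dp, initial_ordering(dp), method = "ols")
    expect_gte(fit_norm(nn), fit_norm(ol) - 1e-12)
    expect_kkt(nn$design, nn$dvec, nn$weights)
  }
})
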