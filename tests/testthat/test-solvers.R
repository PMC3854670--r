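test_that("zero input stops before any selection", {
  A <- matrix(rnorm(40), 5, 8)
  fit <- somp(A, matrix(0, 5, 3), solver_config(K0 = 2))
  expect_length(fit$support, 0)
  expect_equal(fit$coefficients, matrix(0, 8, 3))
  expect_equal(fit$residual_norm, 0)
  expect_length(residual_trace(fit), 0)
})

test_that("an exact single atom is recovered with zero residual", {
  set.seed(11)
  d <- suppressWarnings(src_dictionary(matrix(rnorm(5 * 12), 5, 12),
                                       rep(1:3, each = 4)))
  k <- 7
  Y <- d$matrix[, k] %*% t(rep(1, 4))
  fit <- somp(d, Y, solver_config(K0 = 1))
  expect_equal(fit$support, k)
  expect_equal(fit$residual_norm, 0, tolerance = 1e-12)
  expect_equal(unique(round(fit$coefficients[k, ], 10)), 1)
  expect_equal(residual_trace(fit), 0, tolerance = 1e-12)

  # OMP: unit and scaled coefficients
  f1 <- omp(d, d$matrix[, k], solver_config(K0 = 1))
  expect_equal(f1$support, k)
  expect_equal(f1$coefficients[k, 1], 1, tolerance = 1e-12)
  f3 <- omp(d, 3 * d$matrix[, k], solver_config(K0 = 1))
  expect_equal(f3$support, k)
  expect_equal(f3$coefficients[k, 1], 3, tolerance = 1e-12)
})

test_that("SOMP support matches the exhaustive best-subset oracle", {
  # greedy selection is not globally optimal; agreement holds on most
  # instances, and whenever the support matches the residual vanishes
  hits <- 0L
  for (seed in 1:20) {
    inst <- random_mmv_instance(n = 8, N = 24, s = 5, k = 2, seed = seed)
    fit <- somp(inst$A, inst$Y, solver_config(K0 = 2))
    oracle <- best_subset_support(inst$A, inst$Y, 2)
    if (identical(sort(fit$support), oracle)) {
      hits <- hits + 1L
      expect_lte(fit$residual_norm, 1e-8)
    }
  }
  expect_gte(hits, 16L)
})

test_that("OMP support matches the exhaustive 3-subset oracle", {
  hits <- 0L
  for (seed in 101:115) {
    inst <- random_mmv_instance(n = 12, N = 20, s = 1, k = 3, seed = seed)
    fit <- omp(inst$A, drop(inst$Y), solver_config(K0 = 3))
    oracle <- best_subset_support(inst$A, inst$Y, 3)
    if (identical(sort(fit$support), oracle)) hits <- hits + 1L
  }
  expect_gte(hits, 10L)
})

test_that("residual trace is non-increasing, even on noisy instances", {
  set.seed(21)
  for (i in 1:25) {
    A <- matrix(rnorm(6 * 30), 6, 30)
    Y <- matrix(rnorm(6 * 4), 6, 4)            # pure noise target
    fit <- somp(A, Y, solver_config(K0 = 5))
    tr <- c(sqrt(sum(Y^2)), residual_trace(fit))
    expect_true(all(diff(tr) <= 1e-10))
    expect_equal(fit$residual_norm, tr[length(tr)])
  }
})

test_that("rows outside the support are exactly zero and support is valid", {
  set.seed(31)
  A <- matrix(rnorm(7 * 40), 7, 40)
  Y <- matrix(rnorm(7 * 3), 7, 3)
  fit <- somp(A, Y, solver_config(K0 = 4))
  expect_lte(length(fit$support), 4)
  expect_false(any(duplicated(fit$support)))
  expect_true(all(fit$support %in% 1:40))
  off <- setdiff(1:40, fit$support)
  expect_true(all(fit$coefficients[off, ] == 0))
})

test_that("somp on a one-column matrix and omp agree to machine precision", {
  set.seed(41)
  A <- matrix(rnorm(5 * 30), 5, 30)
  for (i in 1:50) {
    y <- rnorm(5)
    f1 <- omp(A, y, solver_config(K0 = 3))
    f2 <- somp(A, matrix(y, ncol = 1), solver_config(K0 = 3))
    expect_identical(f1$support, f2$support)
    expect_identical(f1$coefficients, f2$coefficients)
    expect_identical(f1$residual_trace, f2$residual_trace)
  }
})

test_that("the first selected atom maximizes the correlation score", {
  set.seed(51)
  for (i in 1:20) {
    A <- matrix(rnorm(6 * 25), 6, 25)
    A <- sweep(A, 2, sqrt(colSums(A^2)), "/")
    Y <- matrix(rnorm(6 * 3), 6, 3)
    fit <- somp(A, Y, solver_config(K0 = 1))
    scores <- sqrt(rowSums((t(A) %*% Y)^2))     # direct scan
    expect_equal(fit$support[1], which.max(scores))
  }
})

test_that("permuting dictionary columns permutes the support identically", {
  set.seed(61)
  A <- matrix(rnorm(6 * 20), 6, 20)
  Y <- matrix(rnorm(6 * 4), 6, 4)
  fit <- somp(A, Y, solver_config(K0 = 3))
  perm <- sample(20)
  fitp <- somp(A[, perm], Y, solver_config(K0 = 3))
  expect_equal(match(fit$support, perm), fitp$support)
  expect_equal(fit$coefficients[perm, ], fitp$coefficients)
})

test_that("noiseless MMV supports are recovered at high rate", {
  hits <- 0L
  for (seed in 1:200) {
    inst <- random_mmv_instance(n = 20, N = 100, s = 9, k = 3,
                                seed = 7000 + seed)
    fit <- somp(inst$A, inst$Y, solver_config(K0 = 3))
    if (identical(sort(fit$support), inst$rows)) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("argmax ties break toward the lowest column index", {
  a <- c(1, 0, 0)
  A <- cbind(a, a, a)                # identical atoms: all tie
  fit <- omp(A, c(2, 0, 0), solver_config(K0 = 1))
  expect_equal(fit$support, 1L)
})

test_that("solver input validation names the offending shapes", {
  A <- matrix(rnorm(20), 5, 4)
  expect_error(somp(A, matrix(0, 4, 2)), "4x2.*5x4")
  expect_error(somp(A, matrix(NA_real_, 5, 1)), "non-finite")
  expect_error(somp(A, matrix(1, 5, 1), solver_config(K0 = 9)),
               "exceeds")
  expect_error(solver_config(K0 = 0), "positive")
  expect_error(solver_config(residual_tol = -1), "non-negative")
})
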