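# Independent oracles, kept deliberately naive.

# Exhaustive best-k-subset least squares: the support minimizing the
# Frobenius residual over all C(N, k) column subsets.
best_subset_support <- function(A, Y, k) {
  Y <- as.matrix(Y)
  combs <- utils::combn(ncol(A), k)
  resid <- apply(combs, 2, function(S) {
    As <- A[, S, drop = FALSE]
    X <- qr.coef(qr(As), Y)
    sqrt(sum((Y - As %*% X)^2))
  })
  sort(combs[, which.min(resid)])
}

# A noiseless row-sparse MMV instance over a Gaussian dictionary.
random_mmv_instance <- function(n, N, s, k, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * N), n, N)
  A <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  rows <- sample(N, k)
  X <- matrix(0, N, s)
  X[rows, ] <- matrix(rnorm(k * s, sd = 1) + sign(rnorm(k * s)), k, s)
  list(A = A, X = X, Y = A %*% X, rows = sort(rows))
}

# A small dictionary whose classes are orthogonal coordinate axes, so class
# membership of any vector is unambiguous.
axis_dictionary <- function(n = 5, per_class = 8, m = 2) {
  A <- matrix(0, n, per_class * m)
  cls <- integer(0)
  for (i in seq_len(m)) {
    cols <- (i - 1) * per_class + seq_len(per_class)
    A[i, cols] <- seq(0.5, 2, length.out = per_class)
    cls <- c(cls, rep(i, per_class))
  }
  suppressWarnings(src_dictionary(A, cls))
}
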