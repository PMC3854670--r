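#' Solver settings for OMP / SOMP
#'
#' @param K0 sparsity level: maximum number of atoms (nonzero rows) the
#'   greedy solver may select. The recommended operating range for M-FISH
#'   classification is `K0 <= 5`.
#' @param q norm index used to score atoms against the residual matrix
#'   (the `l_{0,q}` row-sparsity model); default 2, the Euclidean row norm.
#' @param residual_tol early-stop threshold on the Frobenius norm of the
#'   residual. `NULL` (default) resolves to `1e-10 * ||Y||_F` at solve time.
#' @return a list of class `"solver_config"`.
#' @export
solver_config <- function(K0 = 3L, q = 2, residual_tol = NULL) {
  K0 <- as.integer(K0)
  if (is.na(K0) || K0 < 1L) stop("K0 must be a positive integer")
  if (!is.null(residual_tol) && residual_tol < 0)
    stop("residual_tol must be non-negative")
  if (q <= 0) stop("q must be positive")
  structure(list(K0 = K0, q = q, residual_tol = residual_tol),
            class = "solver_config")
}

.as_dict_matrix <- function(dictionary) {
  if (inherits(dictionary, "src_dictionary")) dictionary$matrix
  else as.matrix(dictionary)
}

#' Simultaneous orthogonal matching pursuit
#'
#' Greedy solver for the multiple-measurement-vector (MMV) sparse model
#' `Y = A X` with a row-sparse coefficient matrix `X`: the `s` columns of
#' `Y` (here, the pixels of one neighborhood) are assumed to share a common
#' support of dictionary atoms. Starting from residual `R0 = Y` and empty
#' support, each iteration selects the atom `a_k` maximizing the q-norm of
#' its correlations with the current residual, `||a_k' R||_q` (ties broken
#' toward the lowest column index), refits the coefficients on the enlarged
#' support by least squares, and recomputes the residual. Iteration stops
#' when `K0` atoms are selected or the residual Frobenius norm falls below
#' `residual_tol`.
#'
#' @param dictionary an [src_dictionary()] or a plain `n x N` matrix.
#' @param Y numeric `n x s` matrix of measurement vectors (a vector is
#'   treated as one column).
#' @param config a [solver_config()].
#' @return Object of class `"somp_fit"`: `coefficients` (`N x s`, rows off
#'   the support exactly zero), `support` (ordered selected atom indices),
#'   `residual_norm`, `iterations`, and the per-iteration residual trace.
#' @seealso [omp()], [residual_trace()]
#' @examples
#' A <- qr.Q(qr(matrix(rnorm(64), 8)))[, 1:6]  # orthonormal atoms
#' Y <- A[, 3] %*% t(rep(1, 4))                # 4 copies of atom 3
#' somp(A, Y, solver_config(K0 = 1))$support
#' @export
somp <- function(dictionary, Y, config = solver_config()) {
  A <- .as_dict_matrix(dictionary)
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1L)
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (nrow(Y) != nrow(A))
    stop("dimension mismatch: Y is ", nrow(Y), "x", ncol(Y),
         " but dictionary is ", nrow(A), "x", ncol(A))
  if (ncol(Y) < 1L) stop("Y must have at least one column")
  if (any(!is.finite(Y))) stop("Y contains non-finite entries")
  if (config$K0 > ncol(A))
    stop("K0 (", config$K0, ") exceeds the number of atoms (", ncol(A), ")")
  tol <- config$residual_tol
  if (is.null(tol)) tol <- 1e-10 * sqrt(sum(Y^2))
  ans <- .somp_cpp(A, Y, config$K0, tol, config$q)
  ans$config <- config
  class(ans) <- "somp_fit"
  ans
}

#' Orthogonal matching pursuit (single measurement vector)
#'
#' The `s = 1` case of [somp()]: greedy sparse coding of one pixel's channel
#' vector. Returns bit-identical support and coefficients to `somp()` on the
#' one-column matrix `cbind(y)`.
#'
#' @inheritParams somp
#' @param y numeric vector of length `n`.
#' @return a `"somp_fit"` (coefficients are `N x 1`).
#' @export
omp <- function(dictionary, y, config = solver_config()) {
  if (!is.null(dim(y)) && ncol(as.matrix(y)) != 1L)
    stop("'y' must be a single vector; use somp() for matrices")
  somp(dictionary, matrix(as.numeric(y), ncol = 1L), config)
}

#' Per-iteration residual norms of a greedy solve
#'
#' @param solution a `"somp_fit"` from [somp()] or [omp()].
#' @return numeric vector, one Frobenius residual norm per greedy iteration
#'   (length 0 if the solver stopped before selecting any atom).
#' @export
residual_trace <- function(solution) {
  stopifnot(inherits(solution, "somp_fit"))
  as.numeric(solution$residual_trace)
}

#' @export
print.somp_fit <- function(x, ...) {
  cat("SOMP fit: ", x$iterations, " iteration(s), support {",
      paste(x$support, collapse = ", "), "}, residual ",
      format(x$residual_norm, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
coef.somp_fit <- function(object, ...) object$coefficients
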