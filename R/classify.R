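#' Sparsity concentration index
#'
#' Measures how much of a sparse solution's l1 mass is concentrated in a
#' single class block of the dictionary:
#' `SCI = (m * max_i ||delta_i(x)||_1 / ||x||_1 - 1) / (m - 1)`,
#' where `delta_i` keeps only the coefficients on class-i columns. Equals 1
#' when all mass sits in one class and 0 when spread uniformly over all `m`
#' classes. For a multi-column (patch) solution the l1 mass is summed over
#' all entries of the class's rows.
#'
#' @param solution a `"somp_fit"` from [omp()] or [somp()].
#' @param dictionary the [src_dictionary()] the solution was computed over.
#' @return a number in `[0, 1]`.
#' @export
sci <- function(solution, dictionary) {
  X <- abs(solution$coefficients)
  tot <- sum(X)
  if (tot == 0) stop("SCI is undefined for an all-zero solution")
  mass <- vapply(dictionary$classes, function(cl)
    sum(X[dictionary$class_of_column == cl, , drop = FALSE]), numeric(1))
  m <- dictionary$m
  if (m == 1L) return(1)
  (m * max(mass) / tot - 1) / (m - 1)
}

# Per-class reconstruction residuals ||Y - A_i X_i|| with X_i the solved
# coefficients restricted to class-i columns (no refit by default; refit
# re-solves least squares on the class's selected atoms alone).
.class_residuals <- function(dictionary, Y, fit, refit = FALSE) {
  res <- rep(sqrt(sum(Y^2)), dictionary$m)
  names(res) <- dictionary$classes
  sup <- fit$support
  if (length(sup) == 0L) return(res)
  supcls <- dictionary$class_of_column[sup]
  for (cl in unique(supcls)) {
    cols <- sup[supcls == cl]
    Ai <- dictionary$matrix[, cols, drop = FALSE]
    Xi <- if (refit) qr.solve(qr(Ai), Y)
          else fit$coefficients[cols, , drop = FALSE]
    res[as.character(cl)] <- sqrt(sum((Y - Ai %*% Xi)^2))
  }
  res
}

.decision <- function(dictionary, Y, fit, refit) {
  res <- .class_residuals(dictionary, Y, fit, refit)
  structure(list(predicted_class = dictionary$classes[which.min(res)],
                 residual_by_class = res, solution = fit),
            class = "src_decision")
}

#' @export
print.src_decision <- function(x, ...) {
  cat("SRC decision: class ", x$predicted_class, " (residual ",
      format(min(x$residual_by_class), digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Classify a single pixel by sparse representation
#'
#' Codes the pixel's channel vector over the dictionary with [omp()], then
#' assigns the class whose columns reconstruct it with the smallest residual
#' `||y - A_i x_i||_2` (classes absent from the support score `||y||_2`).
#'
#' @param dictionary an [src_dictionary()].
#' @param y numeric vector of channel intensities (length `dictionary$n`).
#' @param config a [solver_config()].
#' @param refit refit the class coefficients by least squares on each
#'   class's selected atoms before computing its residual (default `FALSE`:
#'   residuals use the joint solve's coefficients as-is).
#' @return an `"src_decision"`: `predicted_class`, `residual_by_class`
#'   (named by class), and the underlying `"somp_fit"`.
#' @export
classify_pixel <- function(dictionary, y, config = solver_config(),
                           refit = FALSE) {
  fit <- omp(dictionary, y, config)
  .decision(dictionary, matrix(as.numeric(y), ncol = 1L), fit, refit)
}

#' Classify the central pixel of a neighborhood patch
#'
#' Jointly codes all `s` pixels of the patch over the dictionary with
#' [somp()] (they share one row support), then labels the *central* pixel
#' with the class minimizing the joint Frobenius residual
#' `||Y - A_i X_i||_F`.
#'
#' @inheritParams classify_pixel
#' @param patch a `"patch_matrix"` from [extract_patch()], or a plain
#'   `n x s` matrix.
#' @return an `"src_decision"` for the central pixel.
#' @export
classify_patch <- function(dictionary, patch, config = solver_config(),
                           refit = FALSE) {
  Y <- if (inherits(patch, "patch_matrix")) patch$Y else as.matrix(patch)
  fit <- somp(dictionary, Y, config)
  .decision(dictionary, Y, fit, refit)
}

#' Classify every in-mask pixel of a multichannel image
#'
#' Slides a square window over the chromosomal mask and labels each central
#' pixel by [classify_patch()] (or [classify_pixel()] when `s = 1`). Pixels
#' outside the mask are labelled 0. The predicted label image never contains
#' the overlap code 255.
#'
#' @param channels `H x W x n` numeric array of fluorochrome channels.
#' @param mask logical or 0/1 matrix marking the chromosomal region.
#' @param dictionary an [src_dictionary()].
#' @param config a [solver_config()].
#' @param s nominal neighborhood size: an odd side length squared
#'   (1, 9, 25, 49, ...). The recommended size is 9 (a 3x3 window).
#' @param boundary boundary policy for [extract_patch()].
#' @param refit see [classify_pixel()].
#' @return an integer `H x W` label matrix (0 = background).
#' @export
classify_image <- function(channels, mask, dictionary,
                           config = solver_config(), s = 9,
                           boundary = c("shrink", "pad-replicate"),
                           refit = FALSE) {
  boundary <- match.arg(boundary)
  side <- window_side(s)
  mask <- .as_mask(mask)
  if (!all(dim(mask) == dim(channels)[1:2]))
    stop("mask dimensions (", paste(dim(mask), collapse = "x"),
         ") do not match image dimensions (",
         paste(dim(channels)[1:2], collapse = "x"), ")")
  H <- dim(channels)[1]; W <- dim(channels)[2]; n <- dim(channels)[3]
  pred <- matrix(0L, H, W)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(pred)
  if (config$K0 > dictionary$N)
    stop("K0 (", config$K0, ") exceeds the number of atoms (",
         dictionary$N, ")")
  A <- dictionary$matrix
  cls <- dictionary$classes
  K0 <- config$K0
  flat <- matrix(channels, H * W, n)
  for (k in seq_len(nrow(idx))) {
    r0 <- idx[k, 1]; c0 <- idx[k, 2]
    if (side == 1L) {
      Y <- matrix(flat[(c0 - 1L) * H + r0, ], ncol = 1L)
    } else {
      mc <- .patch_members(H, W, mask, r0, c0, side, boundary)
      Y <- t(flat[(mc[, 2] - 1L) * H + mc[, 1], , drop = FALSE])
    }
    tol <- config$residual_tol
    if (is.null(tol)) tol <- 1e-10 * sqrt(sum(Y^2))
    fit <- .somp_cpp(A, Y, K0, tol, config$q)
    res <- .class_residuals(dictionary, Y, fit, refit)
    pred[r0, c0] <- cls[which.min(res)]
  }
  pred
}

.as_mask <- function(mask) {
  if (is.logical(mask)) return(mask)
  mask > 0
}
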