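#' Construct an SRC training dictionary
#'
#' Bundles the training feature matrix `A` (one column per training pixel,
#' one row per fluorochrome channel) with the class label of every column.
#' Columns are partitioned conceptually into per-class blocks
#' `A = [A_1, ..., A_m]`, though columns of one class need not be contiguous.
#' By default atoms are rescaled to unit Euclidean norm — greedy atom
#' selection by correlation magnitude is scale-sensitive, and the unit-norm
#' frame is the standard SRC convention; the original column norms are kept
#' in `$scale`. Class-residual decisions are unchanged by this rescaling.
#'
#' @param x numeric matrix, `n x N`: `n` channel intensities for each of `N`
#'   training pixels.
#' @param classes integer vector of length `N`; the chromosome class
#'   (`1..24`) of each column.
#' @param normalize rescale columns to unit l2 norm (default `TRUE`).
#' @return An object of class `"src_dictionary"`: a list with `matrix`
#'   (possibly normalized), `class_of_column`, `classes` (sorted distinct
#'   labels), `m`, `n`, `N`, `class_sizes` and `scale`.
#' @examples
#' A <- matrix(rnorm(5 * 40), 5, 40)
#' d <- src_dictionary(A, rep(1:4, each = 10))
#' d$class_sizes
#' @export
src_dictionary <- function(x, classes, normalize = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  classes <- as.integer(classes)
  if (length(classes) != ncol(x))
    stop("'classes' must have one label per column of 'x' (", ncol(x),
         " columns, ", length(classes), " labels)")
  if (any(!is.finite(x)))
    stop("dictionary matrix contains non-finite entries")
  if (any(is.na(classes)) || any(classes < 1L))
    stop("class labels must be positive integers")
  nrm <- sqrt(colSums(x^2))
  if (any(nrm == 0))
    stop("dictionary contains all-zero columns: ",
         paste(utils::head(which(nrm == 0), 5L), collapse = ", "))
  if (normalize) x <- sweep(x, 2L, nrm, "/")
  cls <- sort(unique(classes))
  sizes <- as.integer(table(factor(classes, levels = cls)))
  names(sizes) <- cls
  small <- cls[sizes <= nrow(x)]
  if (length(small))
    warning("classes with N_i <= n (fewer training pixels than channels): ",
            paste(small, collapse = ", "))
  structure(list(matrix = x, class_of_column = classes, classes = cls,
                 m = length(cls), n = nrow(x), N = ncol(x),
                 class_sizes = sizes, scale = nrm,
                 normalized = isTRUE(normalize)),
            class = "src_dictionary")
}

#' @export
print.src_dictionary <- function(x, ...) {
  cat("SRC dictionary: ", x$n, " channels x ", x$N, " training pixels, ",
      x$m, " classes\n", sep = "")
  cat("columns per class:\n")
  print(x$class_sizes)
  invisible(x)
}

#' Indices of the columns belonging to one class
#' @param dictionary an [src_dictionary()].
#' @param class integer class label.
#' @return integer vector of column indices.
#' @export
class_columns <- function(dictionary, class) {
  which(dictionary$class_of_column == class)
}

#' Write / read a dictionary as plain text
#'
#' Two CSV files: `<stem>_matrix.csv` holds the (normalized) atom matrix,
#' `<stem>_columns.csv` the per-column class label and original norm.
#'
#' @param dictionary an [src_dictionary()].
#' @param stem path stem without extension.
#' @return `write_dictionary` returns `stem` invisibly; `read_dictionary`
#'   returns the reconstructed `src_dictionary`.
#' @export
write_dictionary <- function(dictionary, stem) {
  utils::write.csv(dictionary$matrix, paste0(stem, "_matrix.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(class = dictionary$class_of_column,
                              scale = dictionary$scale),
                   paste0(stem, "_columns.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(stem) {
  A <- as.matrix(utils::read.csv(paste0(stem, "_matrix.csv")))
  dimnames(A) <- NULL
  tab <- utils::read.csv(paste0(stem, "_columns.csv"))
  d <- src_dictionary(A, tab$class, normalize = FALSE)
  d$scale <- tab$scale
  d
}
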