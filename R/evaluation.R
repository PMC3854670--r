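#' Ratio of correct classification (RCC)
#'
#' `RCC = (# correctly classified pixels) / (# evaluated pixels)`, the
#' standard accuracy measure for chromosomal-region pixel classification.
#' Background (0) and overlap (255) ground-truth pixels are always excluded
#' from the counts; training pixels should be excluded by restricting
#' `evaluated` to the held-out partition (e.g. `fit$test_coords`).
#'
#' @param predicted integer label matrix from [classify_image()] /
#'   [predict.mfish_src()].
#' @param truth ground-truth label matrix (0 / 1–24 / 255 convention).
#' @param evaluated the pixels to score: a logical matrix, or a matrix of
#'   (`row`, `col`) coordinates (extra columns ignored). Default: all
#'   pixels with truth in 1–24.
#' @return Object of class `"rcc_report"`: `overall_rcc`, `per_class_rcc`
#'   (named numeric), `n_evaluated`, and the `confusion` matrix
#'   (rows = truth, cols = predicted).
#' @export
rcc <- function(predicted, truth, evaluated = NULL) {
  if (!all(dim(predicted) == dim(truth)))
    stop("predicted and truth label images differ in shape")
  if (is.null(evaluated)) {
    keep <- which(truth >= 1 & truth <= 24)
  } else if (is.matrix(evaluated) && !is.logical(evaluated)) {
    keep <- (evaluated[, 2] - 1L) * nrow(truth) + evaluated[, 1]
  } else {
    keep <- which(.as_mask(evaluated))
  }
  tr <- as.integer(truth)[keep]
  ok <- tr >= 1L & tr <= 24L          # drop background / overlap
  tr <- tr[ok]
  pr <- as.integer(predicted)[keep][ok]
  if (!length(tr)) stop("no pixels to evaluate")
  cls <- sort(unique(c(tr, pr)))
  conf <- unclass(table(factor(tr, levels = cls),
                        factor(pr, levels = cls)))
  tcls <- sort(unique(tr))
  per <- vapply(tcls, function(cl) mean(pr[tr == cl] == cl), numeric(1))
  names(per) <- tcls
  structure(list(overall_rcc = mean(pr == tr),
                 per_class_rcc = per,
                 n_evaluated = length(tr), confusion = conf),
            class = "rcc_report")
}

#' @export
print.rcc_report <- function(x, digits = 4, ...) {
  cat("RCC: ", format(100 * x$overall_rcc, digits = digits), "% over ",
      x$n_evaluated, " pixels\n", sep = "")
  cat("per-class RCC (%):\n")
  print(round(100 * x$per_class_rcc, 2))
  invisible(x)
}

#' Paired comparison of two classifiers over cells
#'
#' Two-sided paired t-test on per-cell RCC values of two models evaluated
#' on the same cells. When the paired differences have zero variance the
#' degenerate case is reported explicitly: `t = 0, p = 1` if all
#' differences are zero, otherwise `t = +/-Inf, p = 0`.
#'
#' @param rcc_a,rcc_b numeric vectors of per-cell RCC (same length >= 2,
#'   paired by cell; fractions or percent, as long as both match).
#' @return a list: `mean_a`, `sd_a`, `mean_b`, `sd_b`, `t_statistic`,
#'   `p_value`, `df`, `n`, `mean_difference`.
#' @export
paired_model_test <- function(rcc_a, rcc_b) {
  if (length(rcc_a) != length(rcc_b))
    stop("per-cell RCC vectors differ in length (", length(rcc_a), " vs ",
         length(rcc_b), ")")
  if (length(rcc_a) < 2L) stop("need at least 2 paired cells")
  d <- rcc_a - rcc_b
  if (stats::sd(d) == 0) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
  } else {
    ht <- stats::t.test(rcc_a, rcc_b, paired = TRUE)
    t_stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  list(mean_a = mean(rcc_a), sd_a = stats::sd(rcc_a),
       mean_b = mean(rcc_b), sd_b = stats::sd(rcc_b),
       t_statistic = t_stat, p_value = p, df = length(d) - 1L,
       n = length(d), mean_difference = mean(d))
}

# 8-connected labelling support: TRUE where a wrong pixel has at least one
# wrong pixel among its 8 neighbors.
.has_wrong_neighbor <- function(wrong) {
  H <- nrow(wrong); W <- ncol(wrong)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1), 2:(W + 1)] <- wrong
  acc <- matrix(FALSE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- acc | pad[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  }
  acc
}

#' Count isolated misclassification spots
#'
#' Counts 8-connected components of size one among the misclassified
#' in-mask pixels — the scattered single-pixel errors that neighborhood
#' information is meant to suppress. Overlap (255) and background truth
#' pixels are not counted as misclassifications.
#'
#' @param predicted,truth label matrices of the same shape.
#' @param mask chromosomal-region mask (logical or 0/1).
#' @return integer count of singleton error components.
#' @export
isolated_spot_count <- function(predicted, truth, mask) {
  if (!all(dim(predicted) == dim(truth)))
    stop("predicted and truth label images differ in shape")
  mask <- .as_mask(mask)
  wrong <- mask & truth >= 1 & truth <= 24 & predicted != truth
  sum(wrong & !.has_wrong_neighbor(wrong))
}

#' Label the 8-connected components of a binary image
#'
#' Flood-fill labelling with 8-connectivity (diagonal neighbors connect).
#'
#' @param bin logical matrix.
#' @return integer matrix; 0 off the foreground, components numbered from 1.
#' @export
label_components8 <- function(bin) {
  bin <- .as_mask(bin)
  H <- nrow(bin); W <- ncol(bin)
  lab <- matrix(0L, H, W)
  nl <- 0L
  todo <- which(bin)
  for (start in todo) {
    if (lab[start] != 0L) next
    nl <- nl + 1L
    queue <- start
    lab[start] <- nl
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- (p - 1L) %% H + 1L; cc <- (p - 1L) %/% H + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr < 1L || rr > H || c2 < 1L || c2 > W) next
        q <- (c2 - 1L) * H + rr
        if (bin[q] && lab[q] == 0L) { lab[q] <- nl; queue <- c(queue, q) }
      }
    }
  }
  lab
}

#' Paper-style parameter grids
#'
#' The training-fraction, neighborhood-size and sparsity-level grids used
#' for the standard parameter-effect sweeps.
#' @name parameter_grids
#' @export
training_fraction_grid <- c(0.01, 0.03, 0.05, 0.10, 0.15, 0.20, 0.25,
                            0.30, 0.35, 0.40, 0.50)

#' @rdname parameter_grids
#' @export
neighborhood_size_grid <- c(1, 9, 25, 49, 81, 121, 169)

#' @rdname parameter_grids
#' @export
sparsity_level_grid <- 1:10

#' Sweep classifier parameters over simulated or real cells
#'
#' Runs the full fit-and-classify pipeline ([mfish_src()] +
#' [predict.mfish_src()] + [rcc()]) over the cross product of `K0`,
#' `s`, `fraction` and `seeds` for each cell, and returns a long-format
#' results table. Failures of individual runs are recorded in the `error`
#' column and never abort the sweep.
#'
#' @param cells a list of `"mfish_cell"` objects (or a single cell).
#' @param K0,s,fraction numeric vectors defining the grid.
#' @param seeds integer vector of training-sampling seeds.
#' @param ... further arguments to [mfish_src()] (e.g. `sci_threshold`).
#' @return a data.frame with columns `cell`, `K0`, `s`, `fraction`, `seed`,
#'   `rcc` (held-out RCC, `NA` on failure) and `error`.
#' @export
parameter_sweep <- function(cells, K0 = 3, s = c(1, 9), fraction = 0.1,
                            seeds = 1L, ...) {
  if (inherits(cells, "mfish_cell")) cells <- list(cells)
  if (!length(cells) || !length(K0) || !length(s) || !length(fraction) ||
      !length(seeds))
    stop("empty sweep grid")
  grid <- expand.grid(cell = seq_along(cells), K0 = K0, s = s,
                      fraction = fraction, seed = seeds,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    out <- tryCatch({
      cell <- cells[[g$cell]]
      fit <- mfish_src(cell, fraction = g$fraction, seed = g$seed, ...)
      pred <- predict(fit, cell, s = g$s,
                      config = solver_config(K0 = g$K0))
      r <- rcc(pred, cell$truth, fit$test_coords)
      list(rcc = r$overall_rcc, error = NA_character_)
    }, error = function(e) list(rcc = NA_real_,
                                error = conditionMessage(e)))
    data.frame(cell = g$cell, K0 = g$K0, s = g$s, fraction = g$fraction,
               seed = g$seed, rcc = out$rcc, error = out$error,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
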