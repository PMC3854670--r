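# Run code with a private RNG stream, restoring the caller's state.
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Fit an M-FISH sparse-representation classifier
#'
#' Builds the training dictionary by sampling a fraction of the labelled
#' pixels of a cell, per chromosome class, and holds out the remaining
#' labelled pixels as the test partition. Background pixels (label 0) and
#' chromosome-overlap pixels (label 255) are excluded from both sides:
#' overlapping chromosomes carry mixed fluorochrome signatures that the
#' model does not represent.
#'
#' Optionally, candidate training pixels are screened by their sparsity
#' concentration index ([sci()]): each candidate is sparse-coded against the
#' dictionary of the *other* candidates, and candidates whose SCI falls
#' below `sci_threshold` (poorly concentrated, ambiguous pixels) are
#' rejected and replaced by fresh draws from the same class, for at most
#' `sci_retries` rounds; stragglers still failing after the last round are
#' dropped with a warning (a class is never emptied).
#'
#' @param channels `H x W x n` numeric array of fluorochrome channels
#'   (`n = 5` for M-FISH), or an `"mfish_cell"` from [simulate_mfish_cell()]
#'   (its `truth` is then the default `labels`).
#' @param labels integer `H x W` ground-truth label image using the
#'   0 / 1–24 / 255 convention.
#' @param fraction fraction of each class's labelled pixels sampled into
#'   the dictionary, in `(0, 1]`. `ceiling(fraction * N_i)` pixels are drawn
#'   per class.
#' @param seed integer seed making the sampling reproducible.
#' @param sci_threshold SCI screening threshold in `[0, 1]`, or `NULL`
#'   (default) for no screening.
#' @param sci_retries maximum resampling rounds during SCI screening.
#' @param config [solver_config()] used for SCI screening solves.
#' @param normalize unit-normalize dictionary atoms (see
#'   [src_dictionary()]).
#' @param scale_channels apply per-channel min-max scaling (computed over
#'   the labelled pixels) before forming features. Default `FALSE`: raw
#'   intensities are the features.
#' @param classes optional integer vector of expected classes; any with no
#'   labelled pixels are omitted with a warning.
#' @return Object of class `"mfish_src"`: `dictionary`
#'   (an [src_dictionary()]), `train_coords` / `test_coords` (matrices with
#'   columns `row`, `col`, `class`), `fraction`, `seed`, channel scaling
#'   info and the matched call. Use [predict.mfish_src()] to classify
#'   images and [rcc()] to score predictions.
#' @examples
#' cell <- simulate_mfish_cell(image_size = c(48, 48), m = 4,
#'                             noise_sd = 0, seed = 1)
#' fit <- mfish_src(cell, fraction = 0.5, seed = 1)
#' summary(fit)
#' @export
mfish_src <- function(channels, labels = NULL, fraction = 0.1, seed = 1L,
                      sci_threshold = NULL, sci_retries = 5L,
                      config = solver_config(), normalize = TRUE,
                      scale_channels = FALSE, classes = NULL) {
  if (inherits(channels, "mfish_cell")) {
    if (is.null(labels)) labels <- channels$truth
    channels <- channels$channels
  }
  if (is.null(labels)) stop("'labels' is required")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  dims <- dim(channels)
  if (!all(dim(labels) == dims[1:2]))
    stop("label image dimensions do not match the channels")
  H <- dims[1]; W <- dims[2]; n <- dims[3]
  flat <- matrix(channels, H * W, n)
  scale_info <- NULL
  lab <- as.integer(labels)
  labelled <- which(lab >= 1L & lab <= 24L)
  if (!length(labelled)) stop("no labelled chromosome pixels (1-24) found")
  if (scale_channels) {
    lo <- apply(flat[labelled, , drop = FALSE], 2, min)
    hi <- apply(flat[labelled, , drop = FALSE], 2, max)
    rg <- pmax(hi - lo, .Machine$double.eps)
    flat <- sweep(sweep(flat, 2, lo), 2, rg, "/")
    scale_info <- list(lo = lo, range = rg)
  }
  present <- sort(unique(lab[labelled]))
  if (!is.null(classes)) {
    missing_cls <- setdiff(classes, present)
    if (length(missing_cls))
      warning("classes with zero labelled pixels omitted: ",
              paste(missing_cls, collapse = ", "))
    present <- intersect(sort(classes), present)
    labelled <- labelled[lab[labelled] %in% present]
  }

  train <- .with_seed(seed, {
    unlist(lapply(present, function(cl) {
      idx <- labelled[lab[labelled] == cl]
      k <- ceiling(fraction * length(idx))
      if (length(idx) == 1L) idx else sample(idx, k)
    }))
  })

  if (!is.null(sci_threshold)) {
    train <- .with_seed(seed + 1L, {
      .sci_screen(flat, lab, labelled, train, sci_threshold, sci_retries,
                  config, normalize)
    })
  }

  A <- t(flat[train, , drop = FALSE])
  dict <- src_dictionary(A, lab[train], normalize = normalize)
  test <- setdiff(labelled, train)
  to_coords <- function(i)
    cbind(row = (i - 1L) %% H + 1L, col = (i - 1L) %/% H + 1L,
          class = lab[i])
  structure(list(dictionary = dict,
                 train_coords = to_coords(train),
                 test_coords = to_coords(test),
                 fraction = fraction, seed = seed,
                 sci_threshold = sci_threshold,
                 scale_channels = scale_channels, scale_info = scale_info,
                 image_dim = c(H, W), call = match.call()),
            class = "mfish_src")
}

# Leave-one-out SCI screening of candidate training pixels.
.sci_screen <- function(flat, lab, labelled, train, threshold, retries,
                        config, normalize) {
  for (round in seq_len(retries)) {
    M <- t(flat[train, , drop = FALSE])
    d <- src_dictionary(M, lab[train], normalize = normalize)
    bad <- vapply(seq_along(train), function(j) {
      dj <- suppressWarnings(
        src_dictionary(M[, -j, drop = FALSE], lab[train][-j],
                       normalize = normalize))
      fit <- tryCatch(omp(dj, flat[train[j], ], config),
                      error = function(e) NULL)
      if (is.null(fit) || sum(abs(fit$coefficients)) == 0) return(TRUE)
      sci(fit, dj) < threshold
    }, logical(1))
    if (!any(bad)) return(train)
    pool <- setdiff(labelled, train)
    repl <- integer(0)
    for (j in which(bad)) {
      cand <- pool[lab[pool] == lab[train[j]]]
      cand <- setdiff(cand, repl)
      if (length(cand)) repl <- c(repl, sample(cand, 1L)) else repl <- c(repl, train[j])
    }
    train[bad] <- repl
  }
  # final pass: drop survivors that still fail, but never empty a class
  M <- t(flat[train, , drop = FALSE])
  bad <- vapply(seq_along(train), function(j) {
    dj <- suppressWarnings(
      src_dictionary(M[, -j, drop = FALSE], lab[train][-j],
                     normalize = normalize))
    fit <- tryCatch(omp(dj, flat[train[j], ], config),
                    error = function(e) NULL)
    if (is.null(fit) || sum(abs(fit$coefficients)) == 0) return(TRUE)
    sci(fit, dj) < threshold
  }, logical(1))
  if (any(bad)) {
    keep <- !bad
    for (cl in unique(lab[train]))
      if (!any(keep[lab[train] == cl])) keep[lab[train] == cl] <- TRUE
    if (any(!keep))
      warning(sum(!keep), " training pixel(s) below the SCI threshold ",
              "dropped after ", retries, " resampling round(s)")
    train <- train[keep]
  }
  train
}

#' @export
print.mfish_src <- function(x, ...) {
  cat("M-FISH sparse representation classifier\n")
  cat("  dictionary: ", x$dictionary$n, " channels x ", x$dictionary$N,
      " atoms, ", x$dictionary$m, " classes (fraction ", x$fraction,
      ", seed ", x$seed, ")\n", sep = "")
  cat("  held-out test pixels: ", nrow(x$test_coords), "\n", sep = "")
  invisible(x)
}

#' @export
summary.mfish_src <- function(object, ...) {
  d <- object$dictionary
  tab <- data.frame(class = d$classes,
                    train_columns = as.integer(d$class_sizes),
                    test_pixels = as.integer(
                      table(factor(object$test_coords[, "class"],
                                   levels = d$classes))))
  structure(list(table = tab, fraction = object$fraction,
                 seed = object$seed, sci_threshold = object$sci_threshold),
            class = "summary.mfish_src")
}

#' @export
print.summary.mfish_src <- function(x, ...) {
  cat("Training dictionary (fraction ", x$fraction, ", seed ", x$seed,
      if (!is.null(x$sci_threshold))
        paste0(", SCI threshold ", x$sci_threshold), ")\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mfish_src <- function(object, ...) object$dictionary$matrix

#' Classify an image with a fitted M-FISH SRC model
#'
#' Applies [classify_image()] with the model's dictionary. When `newdata`
#' is an `"mfish_cell"` and no mask is given, the mask defaults to the
#' cell's nonzero ground-truth region (or an Otsu threshold of its DAPI
#' channel if no truth is attached).
#'
#' @param object an [mfish_src()] fit.
#' @param newdata an `"mfish_cell"` or an `H x W x n` channel array;
#'   default: classify the pixels of the training cell is not supported —
#'   supply the cell explicitly.
#' @param mask logical chromosomal-region mask (see above for the default).
#' @param s nominal neighborhood size (odd side squared); `s = 1` is the
#'   pixelwise model, `s = 9` the recommended joint model.
#' @param config a [solver_config()].
#' @param ... passed to [classify_image()] (`boundary`, `refit`).
#' @return integer label matrix (0 outside the mask).
#' @export
predict.mfish_src <- function(object, newdata, mask = NULL, s = 9,
                              config = solver_config(), ...) {
  if (inherits(newdata, "mfish_cell")) {
    if (is.null(mask)) {
      mask <- if (!is.null(newdata$truth)) newdata$truth != 0
              else threshold_mask(newdata$dapi)
    }
    newdata <- newdata$channels
  }
  if (is.null(mask)) stop("'mask' is required for a plain channel array")
  if (isTRUE(object$scale_channels)) {
    H <- dim(newdata)[1]; W <- dim(newdata)[2]; n <- dim(newdata)[3]
    flat <- matrix(newdata, H * W, n)
    flat <- sweep(sweep(flat, 2, object$scale_info$lo), 2,
                  object$scale_info$range, "/")
    newdata <- array(flat, c(H, W, n))
  }
  classify_image(newdata, mask, object$dictionary, config = config, s = s,
                 ...)
}
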