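#' Default combinatorial fluorochrome code table
#'
#' Assigns each chromosome class a distinct nonzero binary code over the
#' fluorochrome channels: with `n_fluor` dyes there are `2^n_fluor - 1`
#' usable combinations, so 5 dyes suffice for the 24 human chromosome
#' types. Codes are taken in binary-reflected Gray-code order, so
#' consecutive classes differ in exactly one channel — the hardest
#' adjacency a classifier must separate, and a fixed, documented mapping.
#'
#' @param m number of classes (default 24).
#' @param n_fluor number of fluorochrome channels (default 5).
#' @return Object of class `"label_code_table"`: `codes` (`m x n_fluor`
#'   0/1 matrix, one row per class) and `n_fluor`.
#' @examples
#' default_code_table(m = 3, n_fluor = 2)$codes
#' @export
default_code_table <- function(m = 24L, n_fluor = 5L) {
  m <- as.integer(m); n_fluor <- as.integer(n_fluor)
  if (m < 1L) stop("m must be at least 1")
  if (m > 2L^n_fluor - 1L)
    stop("m = ", m, " classes need more than the ", 2L^n_fluor - 1L,
         " nonzero codes available with ", n_fluor, " fluorochromes")
  gray <- vapply(seq_len(m), function(i) bitwXor(i, bitwShiftR(i, 1L)),
                 integer(1))
  codes <- t(vapply(gray, function(g)
    as.integer(bitwAnd(bitwShiftR(g, 0:(n_fluor - 1L)), 1L)),
    integer(n_fluor)))
  dimnames(codes) <- list(class = seq_len(m), channel = seq_len(n_fluor))
  structure(list(codes = codes, n_fluor = n_fluor),
            class = "label_code_table")
}

#' @export
print.label_code_table <- function(x, ...) {
  cat("fluorochrome code table: ", nrow(x$codes), " classes x ",
      x$n_fluor, " channels\n", sep = "")
  print(x$codes)
  invisible(x)
}

# rasterize a rotated ellipse (chromosome-like elongated blob)
.ellipse_pixels <- function(H, W, cy, cx, a, b, theta) {
  r0 <- max(1L, floor(cy - a)); r1 <- min(H, ceiling(cy + a))
  c0 <- max(1L, floor(cx - a)); c1 <- min(W, ceiling(cx + a))
  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  cc <- rep(c0:c1, each = r1 - r0 + 1L)
  u <- (rr - cy) * cos(theta) + (cc - cx) * sin(theta)
  v <- -(rr - cy) * sin(theta) + (cc - cx) * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  cbind(rr[inside], cc[inside])
}

#' Simulate an M-FISH cell image set
#'
#' Generates a multichannel image emulating combinatorially labelled
#' chromosomes: elongated elliptical blobs (chromosome-like aspect ratios)
#' are placed per class; each blob pixel emits
#' `base_intensity * code[class]` on its class's labelled channels, the
#' per-pixel channel vector is passed through the spectral `crosstalk`
#' matrix, and i.i.d. Gaussian noise of sd `noise_sd` is added per channel
#' (clipped at zero). Where blobs of different classes intersect, pixels
#' are relabelled with the overlap code 255 (up to `overlap_fraction` of
#' the chromosomal region; their signal is the union of the two codes).
#' The DAPI channel carries `base_intensity` on every chromosomal pixel.
#' Fully reproducible from `seed`.
#'
#' @param image_size `c(H, W)` (default 128 x 128).
#' @param m number of chromosome classes (default 24).
#' @param n_fluor number of fluorochrome channels (default 5).
#' @param regions_per_class blobs per class (default 1).
#' @param base_intensity mean on-signal level (default 1).
#' @param noise_sd additive Gaussian sd per channel, same units as
#'   `base_intensity`. The default is the calibration level at which the
#'   pixelwise model scores roughly mid-range RCC (see
#'   [calibration_noise_sd]).
#' @param crosstalk `n_fluor x n_fluor` spectral mixing matrix applied to
#'   every pixel's pre-noise channel vector; identity = no mixing. Must be
#'   diagonally dominant.
#' @param overlap_fraction maximum fraction of chromosomal pixels
#'   relabelled 255 at blob intersections; with 0, colliding placements
#'   are rejected and retried.
#' @param blob_axes length-2 ranges `list(major = c(lo, hi), minor =
#'   c(lo, hi))` of blob semi-axes in pixels.
#' @param seed integer seed (mandatory for reproducibility).
#' @param code_table a [default_code_table()] (defaults to
#'   `default_code_table(m, n_fluor)`).
#' @return Object of class `"mfish_cell"`: `channels` (`H x W x n_fluor`),
#'   `dapi` (`H x W`), `truth` (label matrix, 0 / 1..m / 255),
#'   `code_table`, and `config` (the echoed parameters).
#' @export
simulate_mfish_cell <- function(image_size = c(128L, 128L), m = 24L,
                                n_fluor = 5L, regions_per_class = 1L,
                                base_intensity = 1, noise_sd =
                                  calibration_noise_sd * base_intensity,
                                crosstalk = diag(n_fluor),
                                overlap_fraction = 0.02,
                                blob_axes = list(major = c(7, 12),
                                                 minor = c(2, 3.5)),
                                seed, code_table = NULL) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  crosstalk <- as.matrix(crosstalk)
  if (!all(dim(crosstalk) == n_fluor))
    stop("crosstalk must be ", n_fluor, "x", n_fluor)
  if (any(2 * abs(diag(crosstalk)) < rowSums(abs(crosstalk))))
    stop("crosstalk matrix must be diagonally dominant")
  if (is.null(code_table)) code_table <- default_code_table(m, n_fluor)
  H <- as.integer(image_size[1]); W <- as.integer(image_size[2])
  codes <- code_table$codes

  .with_seed(seed, {
    truth <- matrix(0L, H, W)
    second <- matrix(0L, H, W)       # class of the covering blob at overlap
    for (cl in seq_len(m)) {
      placed <- 0L
      for (b in seq_len(regions_per_class)) {
        for (try in 1:25) {
          a <- stats::runif(1, blob_axes$major[1], blob_axes$major[2])
          bax <- stats::runif(1, blob_axes$minor[1], blob_axes$minor[2])
          th <- stats::runif(1, 0, pi)
          if (H - a <= a + 1 || W - a <= a + 1) { a <- (min(H, W) - 3) / 2 }
          cy <- stats::runif(1, a + 1, H - a)
          cx <- stats::runif(1, a + 1, W - a)
          px <- .ellipse_pixels(H, W, cy, cx, a, bax, th)
          if (nrow(px) == 0L) next
          hit <- truth[px] != 0L & truth[px] != cl
          if (overlap_fraction == 0 && any(hit)) next
          free <- !hit
          truth[px[free, , drop = FALSE]] <- cl
          if (any(hit)) second[px[hit, , drop = FALSE]] <- cl
          placed <- placed + 1L
          break
        }
      }
      if (placed < regions_per_class)
        warning("class ", cl, ": only ", placed, " of ",
                regions_per_class, " blob(s) could be placed")
    }
    # relabel intersections as overlap, capped at overlap_fraction
    ov <- which(second != 0L)
    region_n <- sum(truth != 0L)
    cap <- floor(overlap_fraction * region_n)
    if (length(ov) > cap) {
      keep255 <- if (cap > 0) sample(ov, cap) else integer(0)
      # excess intersection pixels keep the later blob's class
      rest <- setdiff(ov, keep255)
      truth[rest] <- second[rest]
      ov <- keep255
    }
    first_class <- truth[ov]
    truth[ov] <- 255L

    flat <- matrix(0, H * W, n_fluor)
    lab <- as.integer(truth)
    for (cl in seq_len(m)) {
      i <- which(lab == cl)
      if (length(i))
        flat[i, ] <- matrix(base_intensity * codes[cl, ], length(i),
                            n_fluor, byrow = TRUE)
    }
    if (length(ov)) {                 # union signature of the two classes
      uni <- pmax(codes[first_class, , drop = FALSE],
                  codes[second[ov], , drop = FALSE])
      flat[ov, ] <- base_intensity * uni
    }
    flat <- flat %*% t(crosstalk)
    if (noise_sd > 0)
      flat <- flat + matrix(stats::rnorm(length(flat), 0, noise_sd),
                            nrow(flat))
    flat[flat < 0] <- 0
    channels <- array(flat, c(H, W, n_fluor))
    dapi <- matrix(as.numeric(truth != 0L) * base_intensity, H, W)
    if (noise_sd > 0) {
      dapi <- dapi + matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
      dapi[dapi < 0] <- 0
    }
    structure(list(channels = channels, dapi = dapi, truth = truth,
                   code_table = code_table,
                   config = list(image_size = c(H, W), m = m,
                                 n_fluor = n_fluor,
                                 regions_per_class = regions_per_class,
                                 base_intensity = base_intensity,
                                 noise_sd = noise_sd,
                                 crosstalk = crosstalk,
                                 overlap_fraction = overlap_fraction,
                                 blob_axes = blob_axes, seed = seed)),
              class = "mfish_cell")
  })
}

#' @export
print.mfish_cell <- function(x, ...) {
  d <- dim(x$channels)
  cat("M-FISH cell: ", d[1], "x", d[2], ", ", d[3],
      " fluor channels + DAPI\n", sep = "")
  if (!is.null(x$truth))
    cat("  chromosomal pixels: ", sum(x$truth != 0), " (overlap: ",
        sum(x$truth == 255), ")\n", sep = "")
  if (!is.null(x$config$noise_sd))
    cat("  noise sd ", x$config$noise_sd, ", seed ", x$config$seed, "\n",
        sep = "")
  invisible(x)
}

#' Threshold the DAPI channel into a chromosomal mask
#'
#' Global threshold chosen by Otsu's between-class-variance criterion
#' (via \pkg{EBImage}); pixels above the threshold form the mask. A
#' stand-in for a full segmentation of the DAPI counterstain.
#'
#' @param dapi numeric matrix.
#' @return logical mask matrix.
#' @export
threshold_mask <- function(dapi) {
  if (any(!is.finite(dapi))) stop("DAPI image contains non-finite values")
  lo <- min(dapi); hi <- max(dapi)
  if (hi == lo) stop("DAPI image is constant; no threshold exists")
  x01 <- (dapi - lo) / (hi - lo)
  th <- EBImage::otsu(EBImage::Image(x01), range = c(0, 1))
  mask <- x01 > th
  if (!any(mask)) warning("threshold produced an empty mask")
  mask
}

#' Calibration noise level for the synthetic study conditions
#'
#' The additive per-channel noise sd (as a multiple of `base_intensity`)
#' at which the pixelwise sparse classifier on the default simulated cell
#' scores mid-range RCC (around 0.6–0.9), leaving visible headroom for the
#' neighborhood-joint model. Used as the default `noise_sd` of
#' [simulate_mfish_cell()].
#' @export
calibration_noise_sd <- 0.30
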