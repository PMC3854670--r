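#' Convert a nominal neighborhood size to a window side length
#'
#' Neighborhood sizes are squares of odd side lengths (1, 9, 25, 49, 81,
#' 121, 169, ...), i.e. square windows centered on a pixel.
#'
#' @param s nominal neighborhood size.
#' @return the odd integer side length `sqrt(s)`.
#' @export
window_side <- function(s) {
  side <- sqrt(s)
  if (side != round(side) || side %% 2 != 1)
    stop("s must be the square of an odd side length (1, 9, 25, ...), got ",
         s)
  as.integer(side)
}

# Linear pixel indices (column-major, center first then row-major window
# order) of the window members around (r0, c0). Shared by extract_patch and
# the classify_image hot loop so both take identical pixels.
.patch_members <- function(H, W, mask, r0, c0, side, boundary) {
  half <- (side - 1L) %/% 2L
  dr <- rep(-half:half, each = side)     # row-major: row varies slowest
  dc <- rep(-half:half, times = side)
  rr <- r0 + dr; cc <- c0 + dc
  inimg <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
  if (boundary == "shrink") {
    keep <- inimg
    keep[inimg] <- mask[cbind(rr[inimg], cc[inimg])]
    rr <- rr[keep]; cc <- cc[keep]
  } else {
    rr[!inimg] <- r0; cc[!inimg] <- c0
  }
  ctr <- which(rr == r0 & cc == c0)[1]
  ord <- c(ctr, seq_along(rr)[-ctr])
  cbind(row = rr[ord], col = cc[ord])
}

#' Extract the neighborhood matrix around a pixel
#'
#' Collects the channel vectors of the pixels in the `side x side` window
#' centered at `center` into an `n x s` matrix `Y`. The central pixel is
#' always column 1; the remaining in-window pixels follow in row-major
#' order. Under `boundary = "shrink"` (default), pixels outside the image or
#' outside the mask are dropped, so `s` can be smaller than `side^2` near
#' borders — background pixels never contaminate the joint representation.
#' Under `"pad-replicate"`, pixels outside the *image* are replaced by the
#' center's own channel vector (the mask is not applied to neighbors).
#'
#' @param channels `H x W x n` numeric array.
#' @param mask logical matrix (or `NULL` for all-true).
#' @param center `c(row, col)` of the central pixel; must be in the image
#'   and in the mask.
#' @param side odd window side length.
#' @param boundary `"shrink"` or `"pad-replicate"`.
#' @return Object of class `"patch_matrix"`: `Y` (`n x s`), `center`,
#'   `member_coords` (`s x 2`, first row = center), `s`, and `nominal_s`.
#' @export
extract_patch <- function(channels, mask = NULL, center, side = 3L,
                          boundary = c("shrink", "pad-replicate")) {
  boundary <- match.arg(boundary)
  side <- as.integer(side)
  if (side < 1L || side %% 2L != 1L) stop("side must be odd and >= 1")
  H <- dim(channels)[1]; W <- dim(channels)[2]; n <- dim(channels)[3]
  r0 <- as.integer(center[1]); c0 <- as.integer(center[2])
  if (r0 < 1L || r0 > H || c0 < 1L || c0 > W)
    stop("center (", r0, ",", c0, ") is outside the image")
  if (is.null(mask)) mask <- matrix(TRUE, H, W) else mask <- .as_mask(mask)
  if (!mask[r0, c0]) stop("center (", r0, ",", c0, ") is outside the mask")
  mc <- .patch_members(H, W, mask, r0, c0, side, boundary)
  flat <- matrix(channels, H * W, n)
  Y <- t(flat[(mc[, 2] - 1L) * H + mc[, 1], , drop = FALSE])
  structure(list(Y = Y, center = c(r0, c0), member_coords = mc,
                 s = nrow(mc), nominal_s = side^2L),
            class = "patch_matrix")
}

#' @export
print.patch_matrix <- function(x, ...) {
  cat("patch: ", nrow(x$Y), " channels x ", x$s, " pixels (window ",
      sqrt(x$nominal_s), "x", sqrt(x$nominal_s), " at ", x$center[1], ",",
      x$center[2], ")\n", sep = "")
  invisible(x)
}
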