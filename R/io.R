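# On-disk layout of one cell: a directory with a `manifest.yml` naming the
# fluorochrome channel TIFFs (in channel order), the DAPI TIFF, and optional
# truth / mask label TIFFs, plus the config echo needed to regenerate it.

.default_channel_names <- c("F", "G", "A", "R", "Y")

#' Write a label image (0 / 1--24 / 255 convention)
#'
#' Stored as an 8-bit single-channel TIFF, which represents the background
#' (0), class (1..24) and overlap (255) codes exactly.
#'
#' @param labels integer matrix with values in `{0, 1..24, 255}`.
#' @param path output file.
#' @export
write_label_image <- function(labels, path) {
  v <- as.integer(labels)
  bad <- which(!(v %in% c(0:24, 255L)))
  if (length(bad)) stop(.label_error(labels, bad))
  tiff::writeTIFF(matrix(v, nrow(labels)) / 255, path,
                  bits.per.sample = 8L)
  invisible(path)
}

.label_error <- function(labels, bad) {
  H <- nrow(labels)
  r <- (bad - 1L) %% H + 1L; cc <- (bad - 1L) %/% H + 1L
  ex <- utils::head(sprintf("(%d,%d)=%d", r, cc, as.integer(labels)[bad]),
                    5L)
  paste0("label image contains ", length(bad),
         " value(s) outside {0, 1..24, 255}: ", paste(ex, collapse = ", "))
}

#' @rdname write_label_image
#' @return `read_label_image` returns the integer label matrix; values
#'   outside the convention raise an error naming offending pixels.
#' @export
read_label_image <- function(path) {
  v <- round(tiff::readTIFF(path) * 255)
  labels <- matrix(as.integer(v), nrow(v))
  bad <- which(!(labels %in% c(0:24, 255L)))
  if (length(bad)) stop(.label_error(labels, bad))
  labels
}

#' Write a simulated or assembled M-FISH cell to a directory
#'
#' Per-channel 32-bit float TIFFs (intensities scaled into `[0, 1]` by a
#' recorded `intensity_scale`), a DAPI TIFF, an 8-bit truth TIFF, and a
#' `manifest.yml` echoing the channel order, scale, simulation config and
#' fluorochrome code table — everything needed to reload or regenerate the
#' cell.
#'
#' @param cell an `"mfish_cell"` (or a list with `channels`, `dapi`, and
#'   optionally `truth`, `mask`, `config`, `code_table`).
#' @param dir output directory (created if needed).
#' @param channel_names names used in the channel file names; default the
#'   fluorochrome order F, G, A, R, Y.
#' @return `dir`, invisibly.
#' @export
write_mfish_cell <- function(cell, dir,
                             channel_names = .default_channel_names) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(cell$channels)[3]
  channel_names <- channel_names[seq_len(n)]
  scale <- max(cell$channels, cell$dapi, 1e-12)
  files <- sprintf("channel_%d_%s.tif", seq_len(n), channel_names)
  for (i in seq_len(n))
    tiff::writeTIFF(cell$channels[, , i] / scale, file.path(dir, files[i]),
                    bits.per.sample = 32L, reduce = FALSE)
  tiff::writeTIFF(cell$dapi / scale, file.path(dir, "dapi.tif"),
                  bits.per.sample = 32L, reduce = FALSE)
  manifest <- list(channel_files = as.list(files),
                   channel_names = as.list(channel_names),
                   dapi_file = "dapi.tif", intensity_scale = scale)
  if (!is.null(cell$truth)) {
    write_label_image(cell$truth, file.path(dir, "truth.tif"))
    manifest$truth_file <- "truth.tif"
  }
  if (!is.null(cell$mask)) {
    tiff::writeTIFF((cell$mask > 0) * 1, file.path(dir, "mask.tif"),
                    bits.per.sample = 8L)
    manifest$mask_file <- "mask.tif"
  }
  if (!is.null(cell$config)) {
    cfg <- cell$config
    cfg$crosstalk <- as.vector(cfg$crosstalk)
    manifest$config <- cfg
  }
  if (!is.null(cell$code_table)) {
    manifest$code_table <- apply(cell$code_table$codes, 1, paste,
                                 collapse = "")
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  invisible(dir)
}

#' Read an M-FISH cell from a directory
#'
#' Loads the channels named by `manifest.yml` in manifest order (never
#' inferred from file names), the DAPI channel, and the optional truth and
#' mask images, validating that exactly `n_expected` fluor channels are
#' present, that all images agree in shape, and that the truth image uses
#' the 0 / 1–24 / 255 convention.
#'
#' @param dir the cell directory (or a path to its manifest YAML).
#' @param n_expected required number of fluor channels (default 5).
#' @return an `"mfish_cell"` with `channels`, `dapi`, `truth` (or `NULL`),
#'   `mask` (or `NULL`) and the manifest config echo.
#' @export
read_mfish_cell <- function(dir, n_expected = 5L) {
  mfile <- if (dir.exists(dir)) file.path(dir, "manifest.yml") else dir
  if (!file.exists(mfile)) stop("no manifest found at ", mfile)
  base <- dirname(mfile)
  man <- yaml::read_yaml(mfile)
  files <- unlist(man$channel_files)
  if (length(files) != n_expected)
    stop("manifest lists ", length(files), " fluor channel(s); expected ",
         n_expected)
  scale <- if (!is.null(man$intensity_scale)) man$intensity_scale else 1
  chans <- lapply(files, function(f) {
    p <- file.path(base, f)
    if (!file.exists(p)) stop("missing channel file: ", p)
    tiff::readTIFF(p) * scale
  })
  dims <- vapply(chans, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("channel images disagree in shape: ",
         paste(sprintf("%s is %dx%d", files, dims[1, ], dims[2, ]),
               collapse = "; "))
  H <- dims[1, 1]; W <- dims[2, 1]
  channels <- array(unlist(chans), c(H, W, length(chans)))
  dapi <- tiff::readTIFF(file.path(base, man$dapi_file)) * scale
  if (!all(dim(dapi) == c(H, W)))
    stop("DAPI image shape (", paste(dim(dapi), collapse = "x"),
         ") does not match the channels (", H, "x", W, ")")
  truth <- NULL
  if (!is.null(man$truth_file)) {
    truth <- read_label_image(file.path(base, man$truth_file))
    if (!all(dim(truth) == c(H, W)))
      stop("truth image shape does not match the channels")
  }
  mask <- NULL
  if (!is.null(man$mask_file)) {
    mask <- round(tiff::readTIFF(file.path(base, man$mask_file))) > 0
  }
  code_table <- NULL
  if (!is.null(man$code_table)) {
    codes <- do.call(rbind, lapply(man$code_table, function(s)
      as.integer(strsplit(s, "")[[1]])))
    dimnames(codes) <- list(class = seq_len(nrow(codes)),
                            channel = seq_len(ncol(codes)))
    code_table <- structure(list(codes = codes, n_fluor = ncol(codes)),
                            class = "label_code_table")
  }
  structure(list(channels = channels, dapi = dapi, truth = truth,
                 mask = mask, code_table = code_table,
                 config = man$config),
            class = "mfish_cell")
}
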