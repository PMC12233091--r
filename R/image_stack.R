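#' Four-axis image container
#'
#' The internal image model is a 4-axis intensity array indexed
#' `I(t, c, x, y)`: timepoint, channel, row, column. Single images are
#' promoted by inserting singleton axes, so a plain 2D matrix becomes a
#' stack of shape `(1, 1, H, W)`. Intensities must be finite and
#' non-negative; `pixel_size` (micrometres per pixel), when given, must be
#' positive.
#'
#' @param data a 2D matrix, 3D array `(t, x, y)` or 4D array `(t, c, x, y)`
#'   of non-negative finite intensities.
#' @param pixel_size optional micrometres per pixel (positive scalar).
#' @param channel_names optional character vector of channel labels.
#' @return an `image_stack` object.
#' @export
image_stack <- function(data, pixel_size = NULL, channel_names = NULL) {
  if (is.matrix(data)) {
    data <- array(data, dim = c(1, 1, nrow(data), ncol(data)))
  } else if (length(dim(data)) == 3) {
    data <- array(data, dim = c(dim(data)[1], 1, dim(data)[2], dim(data)[3]))
  } else if (length(dim(data)) != 4) {
    stopf("image data must have 2, 3 or 4 axes, got %d", length(dim(data)))
  }
  if (!all(is.finite(data))) stopf("intensities must be finite")
  if (any(data < 0)) stopf("intensities must be non-negative")
  if (!is.null(pixel_size)) {
    if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
      stopf("pixel_size must be a positive scalar (micrometres per pixel)")
    }
  }
  if (!is.null(channel_names) && length(channel_names) != dim(data)[2]) {
    stopf("channel_names length (%d) does not match channel count (%d)",
          length(channel_names), dim(data)[2])
  }
  structure(
    list(data = data, pixel_size = pixel_size, channel_names = channel_names),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d timepoint(s), %d channel(s), %d x %d px", d[1], d[2], d[3], d[4]))
  if (!is.null(x$pixel_size)) cat(sprintf(", %.4g um/px", x$pixel_size))
  cat("\n")
  invisible(x)
}

#' Extract one 2D frame from a stack
#'
#' @param stack an [image_stack()].
#' @param t,c timepoint and channel index (1-based).
#' @return a numeric matrix `(row, col)`.
#' @export
get_frame <- function(stack, t = 1, c = 1) {
  d <- dim(stack$data)
  if (t < 1 || t > d[1] || c < 1 || c > d[2]) {
    stopf("frame (t=%d, c=%d) out of range for a (%d, %d) stack", t, c, d[1], d[2])
  }
  matrix(stack$data[t, c, , ], d[3], d[4])
}

n_timepoints <- function(stack) dim(stack$data)[1]
n_channels <- function(stack) dim(stack$data)[2]
frame_shape <- function(stack) dim(stack$data)[3:4]

#' Read a TIFF stack or plain array dump into the 4-axis image model
#'
#' Multi-page TIFF layouts are ambiguous (pages can enumerate timepoints,
#' channels, or both), so the page layout must be declared explicitly via
#' `axis_order`; there is no silent guessing. For layouts containing both
#' `t` and `c`, one of `n_time` / `n_channels` must be supplied so the page
#' count can be factorized.
#'
#' @param path a TIFF file (single- or multi-page) or a CSV array dump of a
#'   single 2D image.
#' @param axis_order one of `"xy"`, `"txy"`, `"cxy"`, `"tcxy"`, `"ctxy"`;
#'   `"tcxy"` means pages are ordered with `t` slowest.
#' @param n_time,n_channels axis lengths used to factorize the page count.
#' @param pixel_size optional micrometres per pixel, stored as metadata.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, axis_order = "xy", n_time = NULL, n_channels = NULL,
                       pixel_size = NULL) {
  if (!file.exists(path)) stopf("cannot read image: no such file '%s'", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "txt", "tsv")) {
    m <- as.matrix(read.csv(path, header = FALSE))
    storage.mode(m) <- "double"
    return(image_stack(m, pixel_size = pixel_size))
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stopf("cannot read TIFF '%s': %s", path, conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  # Pages with a samples-per-pixel axis carry channels in their 3rd dim.
  if (length(dim(pages[[1]])) == 3) {
    nch <- dim(pages[[1]])[3]
    pages <- unlist(lapply(pages, function(p) {
      lapply(seq_len(nch), function(k) p[, , k])
    }), recursive = FALSE)
    if (axis_order == "xy") axis_order <- "cxy"
    if (axis_order %in% c("txy")) axis_order <- "tcxy"
    n_channels <- nch
  }
  np <- length(pages)
  shp <- dim(pages[[1]])
  lay <- match.arg(axis_order, c("xy", "txy", "cxy", "tcxy", "ctxy"))
  if (lay == "xy") {
    if (np != 1) stopf("layout 'xy' declared but file has %d pages", np)
    tt <- 1; cc <- 1
  } else if (lay == "txy") {
    tt <- np; cc <- 1
  } else if (lay == "cxy") {
    tt <- 1; cc <- np
  } else {
    if (is.null(n_time) && is.null(n_channels)) {
      stopf("layout '%s' needs n_time or n_channels to factorize %d pages", lay, np)
    }
    if (is.null(n_channels)) n_channels <- np / n_time
    if (is.null(n_time)) n_time <- np / n_channels
    if (n_time * n_channels != np || n_time != round(n_time) || n_channels != round(n_channels)) {
      stopf("layout '%s': %d pages inconsistent with t=%s, c=%s", lay, np,
            format(n_time), format(n_channels))
    }
    tt <- as.integer(n_time); cc <- as.integer(n_channels)
  }
  arr <- array(0, dim = c(tt, cc, shp[1], shp[2]))
  for (p in seq_len(np)) {
    if (!identical(dim(pages[[p]]), shp)) stopf("TIFF pages disagree in shape")
    if (lay == "ctxy") {
      t_i <- ((p - 1) %% tt) + 1; c_i <- ((p - 1) %/% tt) + 1
    } else {
      # t slowest for txy/tcxy; degenerate layouts only have one choice
      c_i <- ((p - 1) %% cc) + 1; t_i <- ((p - 1) %/% cc) + 1
    }
    arr[t_i, c_i, , ] <- pages[[p]]
  }
  image_stack(arr, pixel_size = pixel_size)
}

#' Write a stack as a multi-page 16-bit TIFF
#'
#' Pages are written in `tcxy` order (timepoint slowest). Intensities are
#' rounded to integers in `[0, 65535]`; integer-valued stacks therefore
#' round-trip bit-exactly through [read_stack()].
#'
#' @param stack an [image_stack()].
#' @param path output file.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$data)
  if (max(stack$data) > 65535) stopf("intensities exceed the 16-bit range")
  pages <- vector("list", d[1] * d[2])
  p <- 1
  for (t in seq_len(d[1])) {
    for (cc in seq_len(d[2])) {
      pages[[p]] <- round(get_frame(stack, t, cc)) / 65535
      p <- p + 1
    }
  }
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16),
                 error = function(e) stopf("cannot write TIFF '%s': %s", path, conditionMessage(e)))
  invisible(path)
}

#' Write a binary mask as a PNG image
#'
#' @param mask a logical matrix.
#' @param path output file.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  invisible(path)
}
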