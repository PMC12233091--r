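# Global and local (per-spine) translation estimation by phase
# cross-correlation: the normalized cross-power spectrum of two frames is a
# pure phase ramp whose inverse transform peaks at the translation. Subpixel
# refinement evaluates the inverse DFT on an upsampled grid around the
# integer peak (matrix-multiply DFT).

#' Estimate the translation between two frames
#'
#' Returns `(drow, dcol)` such that `moving` equals `reference` translated
#' by that amount; shifting `moving` by the negated estimate aligns it to
#' the reference. Integer shifts are recovered exactly; with `upsample > 1`
#' the peak is refined to a precision of `1/upsample` pixels.
#'
#' @param reference,moving 2D matrices of identical shape, non-constant.
#' @param upsample subpixel upsampling factor (1 = integer precision).
#' @return numeric `(drow, dcol)`.
#' @export
estimate_shift <- function(reference, moving, upsample = 1) {
  if (!identical(dim(reference), dim(moving))) stopf("frame shapes differ")
  if (sd(reference) == 0 || sd(moving) == 0) {
    stopf("undefined shift: constant image content")
  }
  n1 <- nrow(reference); n2 <- ncol(reference)
  f1 <- fft(reference); f2 <- fft(moving)
  cp <- f2 * Conj(f1)
  mag <- Mod(cp)
  # frequencies with numerically vanishing energy carry no phase information;
  # zero them instead of injecting unit-modulus noise into the correlation
  floor_mag <- max(mag) * 1e-10
  q <- cp
  q[mag >= floor_mag] <- cp[mag >= floor_mag] / mag[mag >= floor_mag]
  q[mag < floor_mag] <- 0
  r <- Re(fft(q, inverse = TRUE)) / (n1 * n2)
  pk <- arrayInd(which.max(r), dim(r))
  d <- c(pk[1] - 1, pk[2] - 1)
  if (d[1] > n1 / 2) d[1] <- d[1] - n1
  if (d[2] > n2 / 2) d[2] <- d[2] - n2
  if (upsample > 1) {
    k1 <- c(0:(ceiling(n1 / 2) - 1), -(floor(n1 / 2):1))
    k2 <- c(0:(ceiling(n2 / 2) - 1), -(floor(n2 / 2):1))
    u1 <- d[1] + seq(-1, 1, by = 1 / upsample)
    u2 <- d[2] + seq(-1, 1, by = 1 / upsample)
    e1 <- exp(2i * pi * outer(u1, k1) / n1)   # (len(u1) x n1)
    e2 <- exp(2i * pi * outer(k2, u2) / n2)   # (n2 x len(u2))
    rr <- Re(e1 %*% q %*% e2) / (n1 * n2)
    pk <- arrayInd(which.max(rr), dim(rr))
    d <- c(u1[pk[1]], u2[pk[2]])
  }
  c(drow = d[1], dcol = d[2])
}

#' Global motion correction of a time series
#'
#' Estimates the whole-frame translation of every timepoint against the
#' reference frame on one structural channel, then translates all channels
#' of that timepoint by the negated shift. Exposed regions are filled with
#' zeros and excluded via a per-timepoint validity mask. By default shifts
#' are rounded to integers before application (pixel data stay unresampled);
#' `subpixel = TRUE` applies the fractional shift by bilinear interpolation.
#'
#' @param stack an [image_stack()].
#' @param reference_t reference timepoint (default first).
#' @param channel channel used for estimation.
#' @param upsample subpixel estimation factor.
#' @param subpixel apply fractional shifts by interpolation.
#' @return list with `stack` (corrected), `shifts` (T x 2 matrix, reference
#'   row zero), `valid` (T x H x W logical array).
#' @export
correct_global <- function(stack, reference_t = 1, channel = 1, upsample = 1,
                           subpixel = FALSE) {
  tt <- n_timepoints(stack)
  shape <- frame_shape(stack)
  shifts <- matrix(0, tt, 2)
  valid <- array(TRUE, dim = c(tt, shape[1], shape[2]))
  if (tt < 2) return(list(stack = stack, shifts = shifts, valid = valid))
  ref <- get_frame(stack, reference_t, channel)
  out <- stack
  for (t in seq_len(tt)) {
    if (t == reference_t) next
    d <- estimate_shift(ref, get_frame(stack, t, channel), upsample = upsample)
    if (!subpixel) d <- round(d)
    shifts[t, ] <- d
    vm <- shift_matrix(matrix(TRUE, shape[1], shape[2]), -round(d[1]), -round(d[2]),
                       fill = FALSE)
    valid[t, , ] <- vm
    for (ch in seq_len(n_channels(stack))) {
      f <- get_frame(stack, t, ch)
      g <- if (subpixel) {
        as.matrix(EBImage::translate(f, c(-d[1], -d[2]), bg.col = 0))
      } else {
        shift_matrix(f, -d[1], -d[2], fill = 0)
      }
      out$data[t, ch, , ] <- g
    }
  }
  list(stack = out, shifts = shifts, valid = valid)
}

#' Local (per-spine) motion correction
#'
#' After global correction, the phase cross-correlation is applied to a
#' small window around the spine centre at each timepoint. Instead of
#' shifting pixels, only the spine ROI (and its centre) is shifted: pixel
#' data are never mutated, the spine's genuine changes of shape remain
#' visible, and the recorded local shifts quantify spine motility.
#'
#' @param stack the globally corrected [image_stack()].
#' @param record a `spine_record`.
#' @param window window side in pixels (default twice the head width, i.e.
#'   four times its typical radius).
#' @param reference_t reference timepoint.
#' @param channel estimation channel.
#' @param upsample subpixel estimation factor.
#' @param compensatory optional T x 2 matrix of externally supplied
#'   per-timepoint offsets added on top of the estimated local shifts.
#' @return the updated `spine_record` with `local_shifts` populated.
#' @export
correct_local <- function(stack, record, window = NULL, reference_t = 1,
                          channel = 1, upsample = 1, compensatory = NULL) {
  tt <- n_timepoints(stack)
  shape <- frame_shape(stack)
  ctr <- round(record$center$s0)
  if (is.null(window)) {
    window <- ceiling(2 * head_width(record$head_rois[[1]]))
  }
  half <- max(3, ceiling(window / 2))
  r0 <- max(1, ctr[1] - half); r1 <- min(shape[1], ctr[1] + half)
  c0 <- max(1, ctr[2] - half); c1 <- min(shape[2], ctr[2] + half)
  ref <- get_frame(stack, reference_t, channel)[r0:r1, c0:c1, drop = FALSE]
  shifts <- matrix(0, tt, 2)
  for (t in seq_len(tt)) {
    if (t == reference_t) next
    crop <- get_frame(stack, t, channel)[r0:r1, c0:c1, drop = FALSE]
    shifts[t, ] <- tryCatch(estimate_shift(ref, crop, upsample = upsample),
                            error = function(e) c(0, 0))
  }
  record$local_shifts <- shifts
  if (!is.null(compensatory)) {
    if (!all(dim(compensatory) == c(tt, 2))) stopf("compensatory must be a T x 2 matrix")
    record$compensatory <- as.matrix(compensatory)
  }
  record
}

#' Read a compensatory-motion table
#'
#' A CSV with columns `t`, `drow`, `dcol` (one row per timepoint), e.g.
#' produced by an external pre-registration step.
#'
#' @param path CSV file.
#' @param n_time expected number of timepoints.
#' @return a T x 2 matrix.
#' @export
read_compensatory <- function(path, n_time) {
  df <- read.csv(path)
  if (!all(c("t", "drow", "dcol") %in% names(df))) {
    stopf("compensatory table needs columns t, drow, dcol")
  }
  out <- matrix(0, n_time, 2)
  out[df$t, ] <- as.matrix(df[, c("drow", "dcol")])
  out
}
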