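# Dendritic width calculation and segmentation: Canny edges on the
# median-filtered, thresholded image; per-path-point ellipse growth against
# the edge map; a width-continuity smoothing condition; and pixel-wise
# segmentation metrics.

shifted <- function(m, dr, dc) shift_matrix(m, dr, dc, fill = 0)

#' Canny edge map of the median-filtered, thresholded image
#'
#' The image is median-filtered, and Canny edge detection (Gaussian
#' smoothing at `gaussian_sigma`, Sobel gradients, non-maximum suppression
#' along the quantized gradient direction, hysteresis linking of weak edges
#' to strong ones) is run on the filtered intensities. The threshold enters
#' by restricting the result to the neighbourhood of the thresholded
#' foreground, discarding background speckle edges. Running Canny on the
#' filtered intensities rather than on the binary mask keeps the edge on
#' the true intensity step: binarizing first shifts the boundary outward,
#' because a median filter near a bright plateau returns an upper order
#' statistic of the background noise.
#'
#' @param image 2D intensity matrix.
#' @param gaussian_sigma Canny smoothing scale in pixels.
#' @param filter_size median-filter window (as in [binarize()]).
#' @param threshold numeric cut-off or `"mean"` (as in [binarize()]).
#' @param low,high hysteresis thresholds as fractions of the maximum
#'   gradient magnitude.
#' @return logical edge map (possibly empty).
#' @export
detect_edges <- function(image, gaussian_sigma = 2, filter_size = 5,
                         threshold = "mean", low = 0.1, high = 0.2) {
  med <- median_filter(image, filter_size)
  thr <- if (identical(threshold, "mean")) mean(med) else as.numeric(threshold)
  mask <- med > thr
  e <- canny(med, gaussian_sigma, low, high)
  if (any(mask)) {
    near <- EBImage::dilate(mask * 1L, EBImage::makeBrush(5, "disc")) > 0
    e <- e & near
  }
  e
}

canny <- function(img, sigma = 2, low = 0.1, high = 0.2) {
  g <- if (sigma > 0) EBImage::gblur(img, sigma) else img
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # d/dcol
  ky <- t(kx)                                                 # d/drow
  gx <- EBImage::filter2(g, kx)
  gy <- EBImage::filter2(g, ky)
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax == 0) return(matrix(FALSE, nrow(img), ncol(img)))
  ang <- atan2(gy, gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  # non-maximum suppression along 4 quantized directions
  nms <- matrix(FALSE, nrow(img), ncol(img))
  bins <- list(
    list(sel = (ang < 22.5) | (ang >= 157.5), n1 = c(0, 1),  n2 = c(0, -1)),
    list(sel = ang >= 22.5 & ang < 67.5,      n1 = c(1, 1),  n2 = c(-1, -1)),
    list(sel = ang >= 67.5 & ang < 112.5,     n1 = c(1, 0),  n2 = c(-1, 0)),
    list(sel = ang >= 112.5 & ang < 157.5,    n1 = c(1, -1), n2 = c(-1, 1))
  )
  for (b in bins) {
    m1 <- shifted(mag, b$n1[1], b$n1[2])
    m2 <- shifted(mag, b$n2[1], b$n2[2])
    nms <- nms | (b$sel & mag >= m1 & mag >= m2)
  }
  weak <- nms & (mag >= low * mmax)
  strong <- nms & (mag >= high * mmax)
  if (!any(strong)) return(strong)
  lab <- EBImage::bwlabel(weak)
  keep <- setdiff(unique(lab[strong]), 0)
  weak & matrix(lab %in% keep, nrow(img), ncol(img))
}

#' Grow an ellipse at a path point until it meets an edge
#'
#' At each medial-axis point an ellipse is oriented with its semi-minor
#' axis (preset, small) along the path and its semi-major axis normal to
#' it. The semi-major length is grown one pixel at a time, independently on
#' each side, until the ellipse arc touches an edge pixel. The intersection
#' test samples the arc at <= 1 px spacing over +/-45 degrees about the
#' normal, so -- unlike a single outward ray -- a small gap in the edge map
#' cannot let the growth escape. If no edge is met the growth stops at
#' `max_semi_major` and the side is flagged.
#'
#' @param center `(row, col)` path point.
#' @param direction unit tangent `(drow, dcol)` of the path at `center`.
#' @param edges logical edge map.
#' @param semi_minor preset semi-minor half-axis in pixels.
#' @param max_semi_major growth cap in pixels.
#' @return list with `left`, `right` half-widths (pixels; left = +normal
#'   side) and `flag_left`, `flag_right` marking capped sides.
#' @export
grow_ellipse <- function(center, direction, edges, semi_minor = 2,
                         max_semi_major = 30) {
  if (semi_minor <= 0) stopf("semi_minor must be > 0")
  nr <- nrow(edges); nc <- ncol(edges)
  d <- direction / sqrt(sum(direction^2))
  nrm <- c(-d[2], d[1])
  res <- list()
  for (side in c(1, -1)) {
    ns <- side * nrm
    hit <- NA
    for (a in seq(max(1, ceiling(semi_minor)), max_semi_major)) {
      npts <- max(5L, ceiling(a * pi / 2))
      psi <- seq(-pi / 4, pi / 4, length.out = npts)
      pr <- center[1] + a * cos(psi) * ns[1] + semi_minor * sin(psi) * d[1]
      pc <- center[2] + a * cos(psi) * ns[2] + semi_minor * sin(psi) * d[2]
      ir <- round(pr); ic <- round(pc)
      ok <- ir >= 1 & ir <= nr & ic >= 1 & ic <= nc
      if (any(ok) && any(edges[cbind(ir[ok], ic[ok])])) { hit <- a; break }
    }
    key <- if (side == 1) "left" else "right"
    res[[key]] <- if (is.na(hit)) max_semi_major else hit
    res[[paste0("flag_", key)]] <- is.na(hit)
  }
  res
}

#' Per-point dendritic width profile with the smoothing condition
#'
#' Raw half-widths come from [grow_ellipse()] at every full-rank path
#' point, are scaled by `width_multiplier`, and then pass through the
#' width-continuity smoothing condition: a half-width exceeding the running
#' median of its neighbourhood (window `window` path points) by more than
#' `smoothing_strength x median` is replaced by that running median, which
#' restores width continuity across the footprint of a protrusion. This
#' suppresses the abrupt width spikes produced by spines and filopodia
#' growing out of the shaft; `smoothing_strength = Inf` disables the
#' condition. The window default (25 points, roughly 2.5 um of path at
#' 0.1 um/px) exceeds twice a typical spine footprint so the running median
#' stays anchored to the shaft width while a spine passes.
#'
#' @param path a `medial_axis_path`.
#' @param edges logical edge map (same shape as the source image).
#' @param semi_minor,max_semi_major passed to [grow_ellipse()].
#' @param width_multiplier multiplicative width factor (slider equivalent).
#' @param smoothing_strength smoothing condition strength; larger is more
#'   permissive, `Inf` disables.
#' @param window running-median window (odd).
#' @return a `width_profile` with `half_widths` (n x 2, columns left/right),
#'   `smoothed` (logical flags per point), `semi_minor`, and the two
#'   tuning factors.
#' @export
compute_profile <- function(path, edges, semi_minor = 2, max_semi_major = 30,
                            width_multiplier = 1, smoothing_strength = 0.5,
                            window = 25) {
  fr <- path$full_rank
  n <- nrow(fr)
  if (n < 1) stopf("empty medial-axis path")
  tang <- path_tangents(fr)
  hw <- matrix(0, n, 2)
  capped <- matrix(FALSE, n, 2)
  for (i in seq_len(n)) {
    ge <- grow_ellipse(fr[i, ], tang[i, ], edges, semi_minor, max_semi_major)
    hw[i, ] <- c(ge$left, ge$right)
    capped[i, ] <- c(ge$flag_left, ge$flag_right)
  }
  hw <- pmax(hw * width_multiplier, semi_minor)
  flags <- rep(FALSE, n)
  if (is.finite(smoothing_strength) && n >= 3) {
    k <- min(window, if (n %% 2 == 1) n else n - 1)
    for (s in 1:2) {
      med <- runmed(hw[, s], k, endrule = "median")
      over <- hw[, s] > (1 + smoothing_strength) * med
      hw[over, s] <- med[over]
      flags <- flags | over
    }
  }
  structure(list(half_widths = hw, smoothed = flags, semi_minor = semi_minor,
                 width_multiplier = width_multiplier,
                 smoothing_strength = smoothing_strength,
                 capped = capped),
            class = "width_profile")
}

# Unit tangents along a pixel chain (central differences, one-sided ends).
path_tangents <- function(fr) {
  n <- nrow(fr)
  if (n == 1) return(matrix(c(0, 1), 1, 2))
  tang <- matrix(0, n, 2)
  tang[1, ] <- fr[2, ] - fr[1, ]
  tang[n, ] <- fr[n, ] - fr[n - 1, ]
  if (n > 2) tang[2:(n - 1), ] <- fr[3:n, , drop = FALSE] - fr[1:(n - 2), , drop = FALSE]
  lens <- sqrt(rowSums(tang^2))
  lens[lens == 0] <- 1
  tang / lens
}

#' Dendrite segmentation mask from a path and width profile
#'
#' The segmentation is the union of the per-point ellipses (per-side
#' half-widths along the local normal, `semi_minor` along the tangent),
#' guaranteed to contain every full-rank path pixel. When a stack is
#' supplied, per-(t, c) statistics are computed: luminosity along the
#' medial axis, per-point width in physical units (if `pixel_size` known),
#' and total luminosity of the mask.
#'
#' @param path a `medial_axis_path`.
#' @param profile a `width_profile` matching the path length.
#' @param shape `c(nrow, ncol)` of the image.
#' @param stack optional [image_stack()] for statistics.
#' @return a `dendrite_segmentation` with fields `mask`, `path`, `profile`,
#'   `stats`.
#' @export
build_mask <- function(path, profile, shape, stack = NULL) {
  fr <- path$full_rank
  n <- nrow(fr)
  if (nrow(profile$half_widths) != n) stopf("profile length does not match path")
  tang <- path_tangents(fr)
  mask <- matrix(FALSE, shape[1], shape[2])
  b <- max(profile$semi_minor, 0.5)
  for (i in seq_len(n)) {
    d <- tang[i, ]; nrm <- c(-d[2], d[1])
    aL <- profile$half_widths[i, 1]; aR <- profile$half_widths[i, 2]
    rad <- ceiling(max(aL, aR, b))
    r0 <- max(1, fr[i, 1] - rad); r1 <- min(shape[1], fr[i, 1] + rad)
    c0 <- max(1, fr[i, 2] - rad); c1 <- min(shape[2], fr[i, 2] + rad)
    rr <- r0:r1; cc <- c0:c1
    u <- outer(rr - fr[i, 1], cc - fr[i, 2], function(x, y) x * nrm[1] + y * nrm[2])
    v <- outer(rr - fr[i, 1], cc - fr[i, 2], function(x, y) x * d[1] + y * d[2])
    a <- ifelse(u >= 0, aL, aR)
    inside <- ifelse(a > 0, (u / a)^2, ifelse(u == 0, 0, Inf)) + (v / b)^2 <= 1
    mask[rr, cc] <- mask[rr, cc] | inside
  }
  mask[fr] <- TRUE
  stats <- NULL
  if (!is.null(stack)) {
    tt <- n_timepoints(stack); cc <- n_channels(stack)
    axis_lum <- array(0, dim = c(tt, cc, n))
    total_lum <- matrix(0, tt, cc)
    for (t in seq_len(tt)) for (ch in seq_len(cc)) {
      f <- get_frame(stack, t, ch)
      axis_lum[t, ch, ] <- f[fr]
      total_lum[t, ch] <- sum(f[mask])
    }
    width_px <- rowSums(profile$half_widths)
    stats <- list(axis_luminosity = axis_lum, total_luminosity = total_lum,
                  width_px = width_px,
                  width_um = if (!is.null(stack$pixel_size)) width_px * stack$pixel_size else NULL)
  }
  structure(list(mask = mask, path = path, profile = profile, stats = stats),
            class = "dendrite_segmentation")
}

#' Straight-chord baseline segmentation
#'
#' The naive baseline used to contextualize segmentation scores: a straight
#' chord of fixed physical thickness (default use: 2 um) drawn between the
#' dendrite endpoints. Degenerate case `start == end` yields a single disc
#' of radius half the thickness.
#'
#' @param start,end `(row, col)` endpoints.
#' @param thickness_um chord thickness in micrometres.
#' @param pixel_size micrometres per pixel.
#' @param shape image shape `c(nrow, ncol)`.
#' @return logical mask.
#' @export
straight_baseline <- function(start, end, thickness_um, pixel_size, shape) {
  if (is.null(pixel_size) || !is.finite(pixel_size) || pixel_size <= 0) {
    stopf("straight_baseline needs a positive pixel_size to convert %s um", thickness_um)
  }
  half <- thickness_um / pixel_size / 2
  grid <- as.matrix(expand.grid(row = seq_len(shape[1]), col = seq_len(shape[2])))
  d <- pt_seg_dist(grid, start, end)
  out <- matrix(FALSE, shape[1], shape[2])
  out[grid[d <= half, , drop = FALSE]] <- TRUE
  out
}

#' Pixel-wise segmentation metrics: recall, precision, F1
#'
#' `recall = TP/(TP+FN)`, `precision = TP/(TP+FP)`,
#' `F1 = 2 * precision * recall / (precision + recall)`. Conventions: a
#' metric whose denominator is zero is 0 when the other mask is non-empty;
#' two empty masks score (1, 1, 1).
#'
#' @param predicted,truth logical masks of identical shape.
#' @return named numeric vector `c(recall, precision, f1)`.
#' @export
evaluate_segmentation <- function(predicted, truth) {
  if (!identical(dim(predicted), dim(truth))) stopf("mask shapes differ")
  tp <- sum(predicted & truth)
  fp <- sum(predicted & !truth)
  fn <- sum(!predicted & truth)
  if (tp + fp + fn == 0) return(c(recall = 1, precision = 1, f1 = 1))
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(recall = recall, precision = precision, f1 = f1)
}
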