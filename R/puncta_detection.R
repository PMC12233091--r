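# ROI-scoped fluorescent puncta detection: Laplacian-of-Gaussian blob
# detection with a per-ROI adaptive threshold t_R(t,c) = max(R) * gamma/100,
# scale filtering through the [min_sigma, max_sigma] band, and whole-ROI
# omission when the ROI never rises above the background noise level.

#' Threshold policy for puncta detection
#'
#' Two slider-equivalent percentages set the detection threshold
#' independently for the two ROI kinds: `gamma_dendrite` for dendritic
#' segmented-line ROIs and `gamma_synapse` for spine/soma polygons. The
#' scale band `[min_sigma, max_sigma]` (pixels) restricts which blob sizes
#' are reported, and ROIs whose maximum intensity does not exceed
#' `noise_floor` are skipped entirely.
#'
#' @param gamma_dendrite,gamma_synapse percentages in `[0, 100]`.
#' @param min_sigma,max_sigma Gaussian kernel standard deviations (px).
#' @param n_sigma number of scales sampled (log-spaced).
#' @param noise_floor background intensity level; `NULL` means estimate as
#'   mean + 2 SD of the pixels outside all ROIs.
#' @return a `threshold_policy`.
#' @export
threshold_policy <- function(gamma_dendrite = 30, gamma_synapse = 30,
                             min_sigma = 1.5, max_sigma = 4, n_sigma = 8,
                             noise_floor = 0) {
  if (gamma_dendrite < 0 || gamma_dendrite > 100 ||
      gamma_synapse < 0 || gamma_synapse > 100) {
    stopf("gamma values must lie in [0, 100]")
  }
  if (min_sigma <= 0 || max_sigma < min_sigma) stopf("need 0 < min_sigma <= max_sigma")
  structure(list(gamma_dendrite = gamma_dendrite, gamma_synapse = gamma_synapse,
                 min_sigma = min_sigma, max_sigma = max_sigma,
                 n_sigma = n_sigma, noise_floor = noise_floor),
            class = "threshold_policy")
}

#' Per-ROI adaptive detection threshold
#'
#' `tR = max(R) * gamma / 100` where `R` is the collection of pixel
#' intensities inside the ROI at one (t, c).
#'
#' @param roi_pixels numeric vector of ROI pixel intensities (non-empty).
#' @param gamma percentage in `[0, 100]`.
#' @return the threshold on the intensity scale.
#' @export
roi_threshold <- function(roi_pixels, gamma) {
  if (length(roi_pixels) == 0) stopf("empty ROI: cannot derive a threshold")
  if (gamma < 0 || gamma > 100) stopf("gamma must lie in [0, 100]")
  max(roi_pixels) * gamma / 100
}

log_sigmas <- function(policy) {
  if (policy$min_sigma == policy$max_sigma) return(policy$min_sigma)
  exp(seq(log(policy$min_sigma), log(policy$max_sigma),
          length.out = max(2, policy$n_sigma)))
}

# Gaussian blur that tolerates kernels larger than the image: the image is
# edge-replicated out to the kernel size, blurred, and cropped back.
gblur_safe <- function(image, sigma) {
  need <- 2 * (2 * ceiling(2 * sigma) + 1) + 1
  nr <- nrow(image); nc <- ncol(image)
  if (min(nr, nc) > need) return(EBImage::gblur(image, sigma))
  pr <- max(0, ceiling((need - nr) / 2) + 1)
  pc <- max(0, ceiling((need - nc) / 2) + 1)
  idx_r <- clamp(seq(1 - pr, nr + pr), 1, nr)
  idx_c <- clamp(seq(1 - pc, nc + pc), 1, nc)
  big <- image[idx_r, idx_c, drop = FALSE]
  EBImage::gblur(big, sigma)[pr + seq_len(nr), pc + seq_len(nc), drop = FALSE]
}

# Scale-normalized LoG response stack: 2 * sigma^2 * (-Laplacian(G_sigma * I)).
# The 2 sigma^2 normalization puts the response of a Gaussian blob of
# matching scale on the intensity scale of the image (peak response equals
# the blob amplitude), so tR is directly comparable.
log_response_stack <- function(image, sigmas) {
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  out <- array(0, dim = c(nrow(image), ncol(image), length(sigmas)))
  for (i in seq_along(sigmas)) {
    g <- gblur_safe(image, sigmas[i])
    out[, , i] <- -2 * sigmas[i]^2 * EBImage::filter2(g, lap)
  }
  out
}

# Augment the scale grid with one guard scale on each side. Maxima are only
# accepted at interior scales, so a blob larger than max_sigma (response
# still rising at the band edge) is rejected rather than reported at the
# boundary scale.
guard_sigmas <- function(sigmas) {
  ratio <- if (length(sigmas) > 1) sigmas[2] / sigmas[1] else 1.6
  c(sigmas[1] / ratio, sigmas, sigmas[length(sigmas)] * ratio)
}

# Strict local maxima of the (row, col, scale) response cube above
# `threshold`, searched only where `mask` is TRUE and (when `scale_range`
# is given) only at scale indices inside that range.
find_scale_space_maxima <- function(resp, sigmas, threshold, mask,
                                    scale_range = NULL) {
  dims <- dim(resp)
  cand <- which(resp > threshold)
  if (length(cand) == 0) return(NULL)
  ai <- arrayInd(cand, dims)
  keepmask <- mask[ai[, 1] + (ai[, 2] - 1) * dims[1]]
  if (!is.null(scale_range)) {
    keepmask <- keepmask & ai[, 3] >= scale_range[1] & ai[, 3] <= scale_range[2]
  }
  cand <- cand[keepmask]; ai <- ai[keepmask, , drop = FALSE]
  if (length(cand) == 0) return(NULL)
  ismax <- rep(TRUE, length(cand))
  for (dr in -1:1) for (dc in -1:1) for (ds in -1:1) {
    if (dr == 0 && dc == 0 && ds == 0) next
    nb_r <- ai[, 1] + dr; nb_c <- ai[, 2] + dc; nb_s <- ai[, 3] + ds
    ok <- nb_r >= 1 & nb_r <= dims[1] & nb_c >= 1 & nb_c <= dims[2] &
          nb_s >= 1 & nb_s <= dims[3]
    nb_val <- rep(-Inf, length(cand))
    nb_val[ok] <- resp[cbind(nb_r[ok], nb_c[ok], nb_s[ok])]
    ismax <- ismax & (resp[cand] >= nb_val)
    # ties resolved toward the lexicographically smallest index
    tie <- resp[cand] == nb_val
    if (any(tie)) {
      ord_self <- cand[tie]
      ord_nb <- (nb_s[tie] - 1) * dims[1] * dims[2] + (nb_c[tie] - 1) * dims[1] + nb_r[tie]
      ismax[tie] <- ismax[tie] & (ord_self < ord_nb)
    }
  }
  if (!any(ismax)) return(NULL)
  data.frame(row = ai[ismax, 1], col = ai[ismax, 2],
             sigma = sigmas[ai[ismax, 3]],
             response = resp[cand[ismax]])
}

# Greedy overlap pruning: keep the stronger of any pair of detections
# closer than max(sigma_i, sigma_j).
prune_overlaps <- function(det) {
  if (is.null(det) || nrow(det) <= 1) return(det)
  det <- det[order(-det$response, det$row, det$col), , drop = FALSE]
  keep <- rep(TRUE, nrow(det))
  for (i in seq_len(nrow(det) - 1)) {
    if (!keep[i]) next
    j <- (i + 1):nrow(det)
    dd <- sqrt((det$row[j] - det$row[i])^2 + (det$col[j] - det$col[i])^2)
    lim <- pmax(det$sigma[j], det$sigma[i])
    keep[j][dd < lim & keep[j]] <- FALSE
  }
  det[keep, , drop = FALSE]
}

punctum_stats <- function(image, det) {
  n <- nrow(det)
  mins <- means <- maxs <- numeric(n)
  for (i in seq_len(n)) {
    rad <- det$sigma[i] * sqrt(2)
    r0 <- max(1, floor(det$row[i] - rad)); r1 <- min(nrow(image), ceiling(det$row[i] + rad))
    c0 <- max(1, floor(det$col[i] - rad)); c1 <- min(ncol(image), ceiling(det$col[i] + rad))
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - det$row[i])^2, (cc - det$col[i])^2, "+")
    vals <- image[rr, cc, drop = FALSE][d2 <= rad^2]
    mins[i] <- min(vals); means[i] <- mean(vals); maxs[i] <- max(vals)
  }
  det$radius <- det$sigma * sqrt(2)
  det$min_intensity <- mins
  det$mean_intensity <- means
  det$max_intensity <- maxs
  det
}

empty_puncta <- function() {
  data.frame(row = numeric(0), col = numeric(0), sigma = numeric(0),
             response = numeric(0), radius = numeric(0),
             min_intensity = numeric(0), mean_intensity = numeric(0),
             max_intensity = numeric(0), parent_roi = character(0),
             t = integer(0), c = integer(0), arclength = numeric(0))
}

#' Detect puncta inside a polygon ROI
#'
#' Scale-space LoG maxima whose response reaches the ROI-adaptive threshold
#' `tR` (from [roi_threshold()] on this ROI's pixels) and whose centre lies
#' inside the polygon. The whole ROI is skipped when its maximum intensity
#' does not exceed the policy's `noise_floor`.
#'
#' @param image 2D intensity matrix.
#' @param roi a [roi_polygon()].
#' @param policy a [threshold_policy()].
#' @param gamma threshold percentage (defaults to the policy's synapse
#'   slider).
#' @param parent_id,t,c annotations copied to the output rows.
#' @return a data frame of puncta (possibly empty).
#' @export
detect_in_polygon <- function(image, roi, policy = threshold_policy(),
                              gamma = policy$gamma_synapse,
                              parent_id = "roi", t = 1L, c = 1L) {
  rast <- rasterize_polygon(roi, dim(image))
  if (!any(rast)) return(empty_puncta())
  vals <- image[rast]
  nf <- policy$noise_floor
  if (!is.null(nf) && max(vals) <= nf) return(empty_puncta())
  tr <- roi_threshold(vals, gamma)
  v <- roi$vertices
  pad <- ceiling(3 * policy$max_sigma)
  r0 <- max(1, floor(min(v[, 1])) - pad); r1 <- min(nrow(image), ceiling(max(v[, 1])) + pad)
  c0 <- max(1, floor(min(v[, 2])) - pad); c1 <- min(ncol(image), ceiling(max(v[, 2])) + pad)
  crop <- image[r0:r1, c0:c1, drop = FALSE]
  sigmas <- guard_sigmas(log_sigmas(policy))
  resp <- log_response_stack(crop, sigmas)
  det <- find_scale_space_maxima(resp, sigmas, tr, rast[r0:r1, c0:c1, drop = FALSE],
                                 scale_range = c(2, length(sigmas) - 1))
  if (is.null(det)) return(empty_puncta())
  det$row <- det$row + r0 - 1
  det$col <- det$col + c0 - 1
  det <- det[points_in_polygon(cbind(det$row, det$col), roi), , drop = FALSE]
  if (nrow(det) == 0) return(empty_puncta())
  det <- prune_overlaps(det)
  det <- punctum_stats(image, det)
  det$parent_roi <- parent_id
  det$t <- as.integer(t); det$c <- as.integer(c)
  det$arclength <- NA_real_
  det[, names(empty_puncta())]
}

#' Local rectangles along a dendrite
#'
#' Partitions the dendrite band into consecutive quadrilaterals, one per
#' control-point segment of the medial axis, spanning the local per-side
#' widths. Adjacent quads share their cross-section edge exactly (normals
#' at interior control points are averaged), so the tiling has no gaps or
#' double-covered interiors.
#'
#' @param path a `medial_axis_path`.
#' @param profile a `width_profile` aligned with the path.
#' @return list of 4-vertex [roi_polygon()] quads; attribute `arclength`
#'   gives each quad's starting arclength along the axis.
#' @export
dendrite_rectangles <- function(path, profile) {
  cp <- path$control_points
  fr <- path$full_rank
  k <- nrow(cp)
  if (k < 2) stopf("need at least 2 control points")
  # width and normal at each control point
  idx <- vapply(seq_len(k), function(i) {
    which.min((fr[, 1] - cp[i, 1])^2 + (fr[, 2] - cp[i, 2])^2)
  }, integer(1))
  wL <- pmax(profile$half_widths[idx, 1], 0.5)
  wR <- pmax(profile$half_widths[idx, 2], 0.5)
  segdir <- cp[-1, , drop = FALSE] - cp[-k, , drop = FALSE]
  segdir <- segdir / sqrt(rowSums(segdir^2))
  nrm_at <- matrix(0, k, 2)
  for (i in seq_len(k)) {
    d <- if (i == 1) segdir[1, ] else if (i == k) segdir[k - 1, ] else {
      v <- segdir[i - 1, ] + segdir[i, ]
      if (sum(v^2) < 1e-12) segdir[i, ] else v / sqrt(sum(v^2))
    }
    nrm_at[i, ] <- c(-d[2], d[1])
  }
  arc <- c(0, cumsum(sqrt(rowSums((cp[-1, , drop = FALSE] - cp[-k, , drop = FALSE])^2))))
  quads <- vector("list", k - 1)
  for (i in seq_len(k - 1)) {
    q <- rbind(cp[i, ] + wL[i] * nrm_at[i, ],
               cp[i + 1, ] + wL[i + 1] * nrm_at[i + 1, ],
               cp[i + 1, ] - wR[i + 1] * nrm_at[i + 1, ],
               cp[i, ] - wR[i] * nrm_at[i, ])
    quads[[i]] <- roi_polygon(q)
    attr(quads[[i]], "arc_start") <- arc[i]
  }
  attr(quads, "arclength") <- arc
  quads
}

#' Detect puncta along a dendrite via local rectangles
#'
#' The detection threshold is derived from the pixels of the whole dendrite
#' ROI (union of the local rectangles) with `gamma_dendrite`; detection then
#' runs per rectangle and duplicates across shared edges are removed
#' (centres closer than the larger of the two sigmas keep the stronger
#' response). Each punctum is annotated with its arclength position along
#' the medial axis.
#'
#' @param image 2D intensity matrix.
#' @param path a `medial_axis_path`.
#' @param profile a `width_profile`.
#' @param policy a [threshold_policy()].
#' @param parent_id,t,c annotations copied to the output rows.
#' @return a data frame of puncta.
#' @export
detect_in_dendrite <- function(image, path, profile, policy = threshold_policy(),
                               parent_id = "dendrite", t = 1L, c = 1L) {
  quads <- dendrite_rectangles(path, profile)
  shape <- dim(image)
  union_mask <- matrix(FALSE, shape[1], shape[2])
  for (q in quads) union_mask <- union_mask | rasterize_polygon(q, shape)
  if (!any(union_mask)) return(empty_puncta())
  vals <- image[union_mask]
  nf <- policy$noise_floor
  if (!is.null(nf) && max(vals) <= nf) return(empty_puncta())
  tr <- roi_threshold(vals, policy$gamma_dendrite)
  dets <- list()
  for (i in seq_along(quads)) {
    d <- detect_in_polygon_threshold(image, quads[[i]], policy, tr,
                                     parent_id = parent_id, t = t, c = c)
    if (nrow(d) > 0) dets[[length(dets) + 1]] <- d
  }
  if (length(dets) == 0) return(empty_puncta())
  det <- do.call(rbind, dets)
  det <- prune_overlaps(det)
  cp <- path$control_points
  arc <- c(0, cumsum(sqrt(rowSums((cp[-1, , drop = FALSE] -
                                   cp[-nrow(cp), , drop = FALSE])^2))))
  det$arclength <- vapply(seq_len(nrow(det)), function(j) {
    p <- c(det$row[j], det$col[j])
    best <- Inf; at <- 0
    for (i in seq_len(nrow(cp) - 1)) {
      v <- cp[i + 1, ] - cp[i, ]
      len2 <- sum(v^2)
      tt2 <- clamp(((p[1] - cp[i, 1]) * v[1] + (p[2] - cp[i, 2]) * v[2]) / len2, 0, 1)
      proj <- cp[i, ] + tt2 * v
      dd <- sum((p - proj)^2)
      if (dd < best) { best <- dd; at <- arc[i] + tt2 * sqrt(len2) }
    }
    at
  }, numeric(1))
  rownames(det) <- NULL
  det
}

# Polygon detection against a caller-supplied threshold (shared by the
# dendrite path, where tR comes from the whole-dendrite ROI).
detect_in_polygon_threshold <- function(image, roi, policy, tr, parent_id, t, c) {
  rast <- rasterize_polygon(roi, dim(image))
  if (!any(rast)) return(empty_puncta())
  v <- roi$vertices
  pad <- ceiling(3 * policy$max_sigma)
  r0 <- max(1, floor(min(v[, 1])) - pad); r1 <- min(nrow(image), ceiling(max(v[, 1])) + pad)
  c0 <- max(1, floor(min(v[, 2])) - pad); c1 <- min(ncol(image), ceiling(max(v[, 2])) + pad)
  crop <- image[r0:r1, c0:c1, drop = FALSE]
  sigmas <- guard_sigmas(log_sigmas(policy))
  resp <- log_response_stack(crop, sigmas)
  det <- find_scale_space_maxima(resp, sigmas, tr, rast[r0:r1, c0:c1, drop = FALSE],
                                 scale_range = c(2, length(sigmas) - 1))
  if (is.null(det)) return(empty_puncta())
  det$row <- det$row + r0 - 1
  det$col <- det$col + c0 - 1
  det <- det[points_in_polygon(cbind(det$row, det$col), roi), , drop = FALSE]
  if (nrow(det) == 0) return(empty_puncta())
  det <- prune_overlaps(det)
  det <- punctum_stats(image, det)
  det$parent_roi <- parent_id
  det$t <- as.integer(t); det$c <- as.integer(c)
  det$arclength <- NA_real_
  det[, names(empty_puncta())]
}

#' Per-compartment puncta counts and fractions
#'
#' Tallies puncta per (channel, compartment) from a compartment map (named
#' vector: ROI id -> compartment, e.g. soma vs neurite). Fractions sum to 1
#' per channel; with zero puncta in a channel the fractions are `NA`
#' markers rather than 0/0.
#'
#' @param puncta a puncta data frame.
#' @param compartment_of named character vector mapping `parent_roi` ids to
#'   compartment labels.
#' @return a data frame with `channel`, `compartment`, `count`, `fraction`.
#' @export
localization_fractions <- function(puncta, compartment_of) {
  comps <- sort(unique(unname(compartment_of)))
  if (nrow(puncta) > 0) {
    unmapped <- setdiff(unique(puncta$parent_roi), names(compartment_of))
    if (length(unmapped) > 0) {
      stopf("puncta reference unmapped ROI(s): %s", paste(unmapped, collapse = ", "))
    }
  }
  channels <- if (nrow(puncta) > 0) sort(unique(puncta$c)) else 1L
  rows <- list()
  for (ch in channels) {
    sub <- puncta[puncta$c == ch, , drop = FALSE]
    total <- nrow(sub)
    for (cp in comps) {
      cnt <- sum(compartment_of[sub$parent_roi] == cp)
      rows[[length(rows) + 1]] <- data.frame(
        channel = ch, compartment = cp, count = cnt,
        fraction = if (total > 0) cnt / total else NA_real_
      )
    }
  }
  do.call(rbind, rows)
}
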