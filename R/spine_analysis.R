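# Spine-head ROI generation by eight-ray rule-counter growth, spine-neck
# tracing via the medial-axis machinery on a cropped window, background ROI
# placement, and rule-based morphological classification.

#' Spine centre point
#'
#' @param row,col pixel position (1-based).
#' @param confidence detector confidence in `[0, 1]`; manual centres carry 1.
#' @param flagged user-highlighted structure.
#' @return a `spine_center`.
#' @export
spine_center <- function(row, col, confidence = 1, flagged = FALSE) {
  if (confidence < 0 || confidence > 1) stopf("confidence must lie in [0, 1]")
  structure(list(s0 = c(row = row, col = col), confidence = confidence,
                 flagged = flagged), class = "spine_center")
}

#' Filter detector candidates by confidence
#'
#' Keeps candidates whose confidence is at least `min_confidence`; manual
#' centres (confidence 1) always survive. Order is preserved. Any callable
#' taking a 2D image and returning `(centre, confidence)` pairs can act as
#' the detector feeding this filter.
#'
#' @param candidates list of [spine_center()].
#' @param min_confidence threshold in `[0, 1]`.
#' @return filtered list.
#' @export
filter_detections <- function(candidates, min_confidence) {
  Filter(function(s) s$confidence >= min_confidence || s$confidence == 1, candidates)
}

#' Rule parameters for spine ROI growth
#'
#' @param drop_factor luminosity drop-off factor: a ray point violates the
#'   rule when its intensity falls below `drop_factor * l0` (`l0` =
#'   intensity at the seed).
#' @param n_break counter value at which a ray halts (`c_d >= n`).
#' @param max_extent fall-back rule radius in pixels.
#' @param filter_size median-filter window applied to the image before ray
#'   stepping (1 = raw pixels); the noise-filtering slider equivalent, which
#'   keeps single noisy pixels from halting rays.
#' @return a `spine_params` list.
#' @export
spine_params <- function(drop_factor = 0.4, n_break = 3, max_extent = 30,
                         filter_size = 3) {
  if (drop_factor < 0 || drop_factor > 1) stopf("drop_factor must lie in [0, 1]")
  if (n_break < 1) stopf("n_break must be >= 1")
  list(drop_factor = drop_factor, n_break = n_break, max_extent = max_extent,
       filter_size = filter_size)
}

# Unit direction vectors in fixed order N, NE, E, SE, S, SW, W, NW.
RAY_DIRECTIONS <- local({
  s <- 1 / sqrt(2)
  rbind(N = c(-1, 0), NE = c(-s, s), E = c(0, 1), SE = c(s, s),
        S = c(1, 0), SW = c(s, -s), W = c(0, -1), NW = c(-s, -s))
})

#' Grow a spine-head ROI by eight-ray rule counters
#'
#' From the seed `s0` eight rays step outward along the cardinal and
#' ordinal unit directions: the i-th point of ray d is
#' `s_{i,d} = s0 + i * v_d` (rounded to the pixel grid). Each ray carries an
#' independent violation counter `c_d`, incremented once per broken rule
#' per step among: luminosity drop-off (`I(s_{i,d}) < drop_factor * l0`),
#' other-spine (the point is closer to another centre than to its own),
#' dendrite (the point lies on the dendrite mask), and fall-back
#' (`i > max_extent`). A ray halts once `c_d >= n_break`; its terminal
#' vertex is the last point before the halting step. The eight terminals
#' form the octagonal ROI.
#'
#' @param image 2D intensity matrix.
#' @param s0 a [spine_center()] or `(row, col)` vector.
#' @param all_centers list of other centres (for the other-spine rule).
#' @param dendrite_mask optional logical mask (for the dendrite rule).
#' @param params a [spine_params()].
#' @return a [roi_polygon()] octagon; attribute `ray_radii` holds the
#'   per-direction terminal radii in pixels.
#' @export
grow_spine_roi <- function(image, s0, all_centers = list(),
                           dendrite_mask = NULL, params = spine_params()) {
  ctr <- if (inherits(s0, "spine_center")) s0$s0 else c(row = s0[1], col = s0[2])
  nr <- nrow(image); nc <- ncol(image)
  if (ctr[1] < 1 || ctr[1] > nr || ctr[2] < 1 || ctr[2] > nc) {
    stopf("spine centre (%g, %g) lies outside the image", ctr[1], ctr[2])
  }
  if ((params$filter_size %||% 1) > 1) {
    image <- median_filter(image, params$filter_size)
    params$filter_size <- 1
  }
  l0 <- image[round(ctr[1]), round(ctr[2])]
  if (l0 <= 0) stopf("degenerate seed: zero intensity at (%g, %g)", ctr[1], ctr[2])
  others <- vapply(all_centers, function(s) {
    p <- if (inherits(s, "spine_center")) s$s0 else s
    c(p[1], p[2])
  }, numeric(2))
  if (length(others)) {
    others <- t(others)
    others <- others[abs(others[, 1] - ctr[1]) + abs(others[, 2] - ctr[2]) > 1e-9, ,
                     drop = FALSE]
  } else {
    others <- matrix(numeric(0), 0, 2)
  }
  verts <- matrix(0, 8, 2)
  radii <- numeric(8)
  hard_cap <- params$max_extent + params$n_break + 2
  for (d in 1:8) {
    v <- RAY_DIRECTIONS[d, ]
    cd <- 0
    i_halt <- NA
    oob <- FALSE
    for (i in seq_len(hard_cap)) {
      p <- round(ctr + i * v)
      if (p[1] < 1 || p[1] > nr || p[2] < 1 || p[2] > nc) { i_halt <- i; oob <- TRUE; break }
      viol <- 0
      if (image[p[1], p[2]] < params$drop_factor * l0) viol <- viol + 1
      if (nrow(others) > 0) {
        d_own <- sqrt(sum((p - ctr)^2))
        d_oth <- sqrt(min((others[, 1] - p[1])^2 + (others[, 2] - p[2])^2))
        if (d_oth < d_own) viol <- viol + 1
      }
      if (!is.null(dendrite_mask) && dendrite_mask[p[1], p[2]]) viol <- viol + 1
      if (i > params$max_extent) viol <- viol + 1
      cd <- cd + viol
      if (cd >= params$n_break) { i_halt <- i; break }
    }
    if (is.na(i_halt)) i_halt <- hard_cap + 1
    term_i <- max(i_halt - 1, 0)
    # a ray halted immediately inside the image still spans one pixel so the
    # ROI polygon has positive extent
    if (term_i == 0 && !oob) term_i <- 1
    verts[d, ] <- round(ctr + term_i * v)
    radii[d] <- term_i
  }
  poly <- roi_polygon(verts)
  attr(poly, "ray_radii") <- radii
  attr(poly, "terminals") <- verts  # always 8 x 2, one vertex per direction
  attr(poly, "center") <- ctr
  poly
}

#' Seed-perturbation-averaged spine ROI
#'
#' Runs [grow_spine_roi()] from the seed and from the four one-pixel
#' perturbations in the cardinal directions, then averages the five
#' octagons vertex-wise (per-direction correspondence). Perturbed seeds
#' falling outside the image or on zero intensity are skipped; the average
#' is taken over the remaining polygons.
#'
#' @inheritParams grow_spine_roi
#' @return a [roi_polygon()]; attribute `n_averaged` reports how many
#'   polygons entered the average.
#' @export
average_perturbed_rois <- function(image, s0, all_centers = list(),
                                   dendrite_mask = NULL, params = spine_params()) {
  ctr <- if (inherits(s0, "spine_center")) s0$s0 else c(row = s0[1], col = s0[2])
  if ((params$filter_size %||% 1) > 1) {
    image <- median_filter(image, params$filter_size)
    params$filter_size <- 1
  }
  seeds <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  acc <- NULL; count <- 0
  for (k in seq_len(nrow(seeds))) {
    seed <- ctr + seeds[k, ]
    poly <- tryCatch(
      grow_spine_roi(image, seed, all_centers, dendrite_mask, params),
      error = function(e) NULL
    )
    if (is.null(poly)) {
      if (k == 1) stopf("spine ROI growth failed at the seed (%g, %g)", ctr[1], ctr[2])
      next
    }
    term <- attr(poly, "terminals")  # per-direction correspondence, always 8 x 2
    acc <- if (is.null(acc)) term else acc + term
    count <- count + 1
  }
  out <- roi_polygon(acc / count)
  attr(out, "n_averaged") <- count
  attr(out, "terminals") <- acc / count
  attr(out, "center") <- ctr
  out
}

#' Place a local-background ROI near a spine
#'
#' Translates a copy of the spine ROI along a deterministic outward spiral
#' (starting at 1.5x the head circumradius, 2 px radial steps, 16 angles
#' per ring) to the first position where it overlaps no occupied pixel and
#' stays in bounds.
#'
#' @param spine_roi a [roi_polygon()].
#' @param occupied logical matrix marking all claimed pixels (every ROI
#'   plus the dendrite mask).
#' @param shape image shape `c(nrow, ncol)`.
#' @param max_radius search cut-off in pixels.
#' @return the translated [roi_polygon()].
#' @export
place_background <- function(spine_roi, occupied, shape, max_radius = 50) {
  ctr <- polygon_centroid(spine_roi)
  circ <- polygon_circumradius(spine_roi)
  for (r in seq(ceiling(1.5 * circ), max_radius, by = 2)) {
    for (th in 2 * pi * (0:15) / 16) {
      dr <- round(r * cos(th)); dc <- round(r * sin(th))
      cand <- translate_roi(spine_roi, dr, dc)
      v <- cand$vertices
      if (min(v[, 1]) < 1 || min(v[, 2]) < 1 ||
          max(v[, 1]) > shape[1] || max(v[, 2]) > shape[2]) next
      rast <- rasterize_polygon(cand, shape)
      if (!any(rast & occupied)) return(cand)
    }
  }
  stopf("no unoccupied background position within %d px of the spine", max_radius)
}

#' Trace and segment a spine neck
#'
#' Reuses the medial-axis machinery on a small window: the start point is
#' the spine centre and the end point the nearest dendrite-mask pixel. The
#' window is binarized, a cost field built, and the shortest path traced;
#' the neck is then segmented with the dendritic width machinery and any
#' overlap with the spine-head ROI removed. Failure to find an admissible
#' path (unilluminated neck) or a path shorter than `min_length` (spine
#' flush with the dendrite) is reported as an absence marker, not an error.
#'
#' @param image 2D intensity matrix.
#' @param s0 a [spine_center()] or `(row, col)`.
#' @param head_roi the spine-head [roi_polygon()].
#' @param dendrite a `dendrite_segmentation` (or a logical dendrite mask).
#' @param filter_size,threshold binarization parameters for the window.
#' @param semi_minor neck ellipse semi-minor preset (necks are thin).
#' @param min_length minimum neck path length in pixels.
#' @param margin window margin around the spine-dendrite span.
#' @return a `spine_neck` (fields `path`, `roi`, `mask`, `neck_width`,
#'   `length`) or a `neck_absent` marker with a `reason`.
#' @export
trace_neck <- function(image, s0, head_roi, dendrite, filter_size = 3,
                       threshold = "mean", semi_minor = 1, min_length = 5,
                       margin = 15) {
  ctr <- round(if (inherits(s0, "spine_center")) s0$s0 else c(s0[1], s0[2]))
  dmask <- if (inherits(dendrite, "dendrite_segmentation")) dendrite$mask else dendrite
  absent <- function(reason) structure(list(reason = reason), class = "neck_absent")
  if (dmask[ctr[1], ctr[2]]) return(absent("spine centre lies on the dendrite"))
  dpix <- which(dmask, arr.ind = TRUE)
  if (nrow(dpix) == 0) return(absent("no dendrite mask"))
  d2 <- (dpix[, 1] - ctr[1])^2 + (dpix[, 2] - ctr[2])^2
  endp <- dpix[which.min(d2), ]
  r0 <- max(1, min(ctr[1], endp[1]) - margin); r1 <- min(nrow(image), max(ctr[1], endp[1]) + margin)
  c0 <- max(1, min(ctr[2], endp[2]) - margin); c1 <- min(ncol(image), max(ctr[2], endp[2]) + margin)
  crop <- image[r0:r1, c0:c1, drop = FALSE]
  off <- c(r0 - 1, c0 - 1)
  bm <- suppressWarnings(binarize(crop, filter_size, threshold))
  if (!any(bm$mask)) return(absent("neck not illuminated"))
  cf <- build_cost_field(bm)
  sp <- tryCatch(
    shortest_path(cf, ctr - off, endp - off, downsample_trigger = Inf),
    error = function(e) NULL
  )
  if (is.null(sp)) return(absent("no admissible path between spine and dendrite"))
  if (nrow(sp$full_rank) < min_length) return(absent("spine flush with dendrite"))
  edges <- detect_edges(crop, gaussian_sigma = 1, filter_size = filter_size,
                        threshold = threshold)
  prof <- compute_profile(sp, edges, semi_minor = semi_minor,
                          max_semi_major = 10, smoothing_strength = 0.5)
  seg <- build_mask(sp, prof, dim(crop))
  neck_mask <- matrix(FALSE, nrow(image), ncol(image))
  neck_mask[r0:r1, c0:c1] <- seg$mask
  head_rast <- rasterize_polygon(head_roi, dim(image))
  neck_mask <- neck_mask & !head_rast & !dmask
  if (sum(neck_mask) < 3) return(absent("neck segmentation empty after head removal"))
  path_global <- sweep(sp$full_rank, 2, -off)
  cp_global <- sweep(sp$control_points, 2, -off)
  on_neck <- neck_mask[path_global]
  widths <- rowSums(prof$half_widths)
  # lower-quartile width of the stalk: robust to the flared sections where
  # the neck meets the head and the shaft
  nw <- if (any(on_neck)) {
    unname(stats::quantile(widths[on_neck], 0.25))
  } else unname(stats::quantile(widths, 0.25))
  hull_pts <- which(neck_mask, arr.ind = TRUE)
  roi <- if (nrow(unique(hull_pts)) >= 3) {
    h <- chull(hull_pts[, 2], hull_pts[, 1])
    tryCatch(roi_polygon(hull_pts[h, , drop = FALSE]), error = function(e) NULL)
  } else NULL
  structure(list(path = segmented_line(cp_global, widths = widths[
                   vapply(seq_len(nrow(cp_global)), function(i) {
                     which.min((path_global[, 1] - cp_global[i, 1])^2 +
                               (path_global[, 2] - cp_global[i, 2])^2)
                   }, integer(1))]),
                 full_path = path_global,
                 roi = roi, mask = neck_mask,
                 neck_width = nw,
                 length = polyline_arclength(path_global)),
            class = "spine_neck")
}

#' Classify a spine from its neck and head widths
#'
#' Four morphological classes from the neck-width (NW) to head-width (HW)
#' ratio: no distinct neck (`NW = 0`) is stubby; `NW/HW < 0.5` is mushroom;
#' a ratio between 0.5 and 1.1 (inclusive) is thin; `NW/HW > 1.1` is an
#' outlier.
#'
#' @param NW neck width (>= 0); 0 when no neck was found.
#' @param HW head width (> 0).
#' @return one of `"stubby"`, `"mushroom"`, `"thin"`, `"outlier"`.
#' @export
classify_spine <- function(NW, HW) {
  if (!is.finite(HW) || HW <= 0) stopf("head width must be > 0")
  if (!is.finite(NW) || NW < 0) stopf("neck width must be >= 0")
  if (NW == 0) return("stubby")
  ratio <- NW / HW
  if (ratio < 0.5) "mushroom" else if (ratio <= 1.1) "thin" else "outlier"
}

#' Head width of a spine ROI
#'
#' For ray-grown octagons the head width is the median of the four
#' opposite-ray spans (N-S, NE-SW, E-W, SE-NW). The median makes the
#' estimate robust to the one ray that runs down the bright spine neck
#' toward the dendrite, which would otherwise dominate a maximal-caliper
#' estimate and push necked spines toward the mushroom class. For arbitrary
#' polygons the maximal vertex-to-vertex caliper is returned.
#'
#' @param roi a [roi_polygon()].
#' @return head width in pixels.
#' @export
head_width <- function(roi) {
  term <- attr(roi, "terminals")
  if (!is.null(term) && nrow(term) == 8) {
    spans <- vapply(1:4, function(d) {
      sqrt(sum((term[d, ] - term[d + 4, ])^2))
    }, numeric(1))
    return(median(spans))
  }
  v <- roi$vertices
  sqrt(max(cross_dist2(v, v)))
}

#' Assemble a spine record
#'
#' In luminosity mode one ROI is grown on the per-pixel temporal maximum
#' projection (covering the spine's maximal extent over the whole series);
#' in area mode an ROI is grown independently per timepoint.
#'
#' @param stack an [image_stack()].
#' @param center a [spine_center()].
#' @param all_centers all spine centres (other-spine rule).
#' @param dendrite a `dendrite_segmentation` or `NULL`.
#' @param mode `"luminosity"` or `"area"`.
#' @param channel structural channel index.
#' @param params a [spine_params()].
#' @param trace_necks attempt neck tracing.
#' @return a `spine_record`.
#' @export
make_spine_record <- function(stack, center, all_centers = list(),
                              dendrite = NULL, mode = c("luminosity", "area"),
                              channel = 1, params = spine_params(),
                              trace_necks = TRUE) {
  mode <- match.arg(mode)
  tt <- n_timepoints(stack)
  dmask <- if (!is.null(dendrite)) dendrite$mask else NULL
  if (mode == "luminosity") {
    proj <- get_frame(stack, 1, channel)
    if (tt > 1) for (t in 2:tt) proj <- pmax(proj, get_frame(stack, t, channel))
    head_rois <- list(average_perturbed_rois(proj, center, all_centers, dmask, params))
  } else {
    head_rois <- lapply(seq_len(tt), function(t) {
      average_perturbed_rois(get_frame(stack, t, channel), center, all_centers,
                             dmask, params)
    })
  }
  neck <- NULL
  nw <- 0
  if (trace_necks && !is.null(dendrite)) {
    neck <- trace_neck(get_frame(stack, 1, channel), center, head_rois[[1]], dendrite)
    if (inherits(neck, "spine_neck")) nw <- neck$neck_width
  }
  hw <- head_width(head_rois[[1]])
  structure(list(center = center, head_rois = head_rois, mode = mode,
                 neck = neck, neck_width = nw, head_w = hw,
                 class_label = classify_spine(nw, hw),
                 local_shifts = matrix(0, tt, 2),
                 compensatory = matrix(0, tt, 2),
                 background_roi = NULL),
            class = "spine_record")
}

head_roi_at <- function(record, t) {
  roi <- if (record$mode == "luminosity") record$head_rois[[1]] else record$head_rois[[t]]
  sh <- record$local_shifts[t, ] + record$compensatory[t, ]
  if (any(sh != 0)) roi <- translate_roi(roi, sh[1], sh[2])
  roi
}

#' Per-timepoint, per-channel spine statistics
#'
#' Mean and integrated head luminosity, head area (px^2 and um^2 when the
#' pixel size is known), background-corrected luminosity (head mean minus
#' background-ROI mean), neck length and mean neck luminosity when a neck
#' exists, and the class label. ROIs are evaluated at their motion-corrected
#' positions (local + compensatory shifts).
#'
#' @param record a `spine_record`.
#' @param stack an [image_stack()].
#' @param id entity identifier used in the output table.
#' @return a data frame with one row per (t, c).
#' @export
spine_stats <- function(record, stack, id = "spine") {
  tt <- n_timepoints(stack); cc <- n_channels(stack)
  shape <- frame_shape(stack)
  rows <- list()
  for (t in seq_len(tt)) {
    roi <- head_roi_at(record, t)
    rast <- rasterize_polygon(roi, shape)
    area_px <- polygon_area(roi)
    bg_rast <- if (!is.null(record$background_roi)) {
      rasterize_polygon(record$background_roi, shape)
    } else NULL
    for (ch in seq_len(cc)) {
      f <- get_frame(stack, t, ch)
      mean_lum <- if (any(rast)) mean(f[rast]) else NA_real_
      int_lum <- sum(f[rast])
      bg <- if (!is.null(bg_rast) && any(bg_rast)) mean(f[bg_rast]) else NA_real_
      neck_lum <- if (inherits(record$neck, "spine_neck") && any(record$neck$mask)) {
        mean(f[record$neck$mask])
      } else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        id = id, t = t, c = ch,
        mean_luminosity = mean_lum,
        integrated_luminosity = int_lum,
        area_px2 = area_px,
        area_um2 = if (!is.null(stack$pixel_size)) area_px * stack$pixel_size^2 else NA_real_,
        background_luminosity = bg,
        corrected_luminosity = if (is.na(bg)) NA_real_ else mean_lum - bg,
        neck_length_px = if (inherits(record$neck, "spine_neck")) record$neck$length else NA_real_,
        neck_luminosity = neck_lum,
        neck_width = record$neck_width,
        head_width = record$head_w,
        class_label = record$class_label,
        local_shift_row = record$local_shifts[t, 1],
        local_shift_col = record$local_shifts[t, 2]
      )
    }
  }
  do.call(rbind, rows)
}
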