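# Synthetic ground-truthed image generator. Structures are rendered as
# intensity plateaus (tube-like dendrite of known centreline and width,
# disc spine heads with rectangular necks) plus Gaussian puncta; frames are
# then drifted and corrupted by additive Gaussian noise and optional
# salt-and-pepper noise. Plateau rendering keeps the ground-truth masks
# unambiguous. Identical spec + seed gives bit-identical output.

#' Specify a synthetic fixture
#'
#' All geometry is in the internal `(row, col)` pixel convention. The SNR
#' convention is `(structure mean - background mean) / noise SD`.
#'
#' @param shape image shape `c(nrow, ncol)`.
#' @param pixel_size micrometres per pixel.
#' @param background background intensity level.
#' @param dendrite `NULL` or list with `points` (k x 2 centreline control
#'   points), `width` (full width in px, scalar or per control point),
#'   `intensity`.
#' @param spines list of lists with `center`, `radius`, `intensity`, and
#'   optional `neck_length`, `neck_width` (0 = no neck / stubby),
#'   `wander` (T x 2 per-frame extra displacement).
#' @param puncta list of lists with `center`, `sigma`, `amplitude`,
#'   optional `channel` and `compartment`.
#' @param noise list with `gaussian_sd` and optional `sp_density`,
#'   `sp_amplitude` (salt-and-pepper).
#' @param drift `NULL` or T x 2 matrix of per-frame integer global shifts.
#' @param n_time,n_channels stack dimensions.
#' @param seed RNG seed fixing every random draw.
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(shape = c(128, 196), pixel_size = 0.1, background = 20,
                         dendrite = NULL, spines = list(), puncta = list(),
                         noise = list(gaussian_sd = 0, sp_density = 0,
                                      sp_amplitude = NULL),
                         drift = NULL, n_time = 1, n_channels = 1, seed = 1) {
  structure(list(shape = shape, pixel_size = pixel_size, background = background,
                 dendrite = dendrite, spines = spines, puncta = puncta,
                 noise = noise, drift = drift, n_time = n_time,
                 n_channels = n_channels, seed = seed),
            class = "fixture_spec")
}

render_tube_mask <- function(shape, points, width) {
  grid <- as.matrix(expand.grid(row = seq_len(shape[1]), col = seq_len(shape[2])))
  if (length(width) == 1) {
    d <- pt_polyline_dist(grid, as.matrix(points))
    keep <- d <= width / 2
  } else {
    # per-control-point width, linearly interpolated per segment
    pts <- as.matrix(points)
    keep <- rep(FALSE, nrow(grid))
    for (i in seq_len(nrow(pts) - 1)) {
      v <- pts[i + 1, ] - pts[i, ]
      len2 <- sum(v^2)
      tpar <- clamp(((grid[, 1] - pts[i, 1]) * v[1] + (grid[, 2] - pts[i, 2]) * v[2]) / len2, 0, 1)
      projr <- pts[i, 1] + tpar * v[1]; projc <- pts[i, 2] + tpar * v[2]
      dd <- sqrt((grid[, 1] - projr)^2 + (grid[, 2] - projc)^2)
      w <- width[i] + tpar * (width[i + 1] - width[i])
      keep <- keep | dd <= w / 2
    }
  }
  out <- matrix(FALSE, shape[1], shape[2])
  out[grid[keep, , drop = FALSE]] <- TRUE
  out
}

disc_mask <- function(shape, center, radius) {
  grid <- as.matrix(expand.grid(row = seq_len(shape[1]), col = seq_len(shape[2])))
  d2 <- (grid[, 1] - center[1])^2 + (grid[, 2] - center[2])^2
  out <- matrix(FALSE, shape[1], shape[2])
  out[grid[d2 <= radius^2, , drop = FALSE]] <- TRUE
  out
}

# Rectangle of given width from point a toward point b.
band_mask <- function(shape, a, b, width) {
  grid <- as.matrix(expand.grid(row = seq_len(shape[1]), col = seq_len(shape[2])))
  d <- pt_seg_dist(grid, a, b)
  out <- matrix(FALSE, shape[1], shape[2])
  out[grid[d <= width / 2, , drop = FALSE]] <- TRUE
  out
}

#' Render a synthetic fixture to an image stack plus ground truth
#'
#' @param spec a [fixture_spec()].
#' @return list with `stack` (an [image_stack()], rounded to integer
#'   intensities) and `truth` (dendrite mask, centreline chain, widths,
#'   spine masks and centres, neck masks, puncta positions and sigmas,
#'   per-frame shifts, measured SNR).
#' @export
render_fixture <- function(spec) {
  set.seed(spec$seed)
  shape <- spec$shape
  tt <- spec$n_time; nch <- spec$n_channels
  drift <- if (is.null(spec$drift)) matrix(0, tt, 2) else spec$drift
  if (nrow(drift) != tt) stopf("drift must have one row per timepoint")

  centreline <- NULL; dend_mask <- matrix(FALSE, shape[1], shape[2])
  if (!is.null(spec$dendrite)) {
    pts <- as.matrix(spec$dendrite$points)
    if (any(pts < 1) || any(pts[, 1] > shape[1]) || any(pts[, 2] > shape[2])) {
      stopf("dendrite control points out of bounds")
    }
    dend_mask <- render_tube_mask(shape, pts, spec$dendrite$width)
    centreline <- interpolate_path(pts)
  }
  spine_masks <- list(); neck_masks <- list(); spine_centers <- list()
  for (si in seq_along(spec$spines)) {
    s <- spec$spines[[si]]
    if (s$center[1] < 1 || s$center[1] > shape[1] ||
        s$center[2] < 1 || s$center[2] > shape[2]) stopf("spine %d out of bounds", si)
    spine_masks[[si]] <- disc_mask(shape, s$center, s$radius)
    nw <- if (is.null(s$neck_width)) 0 else s$neck_width
    if (nw > 0 && !is.null(centreline)) {
      d2 <- (centreline[, 1] - s$center[1])^2 + (centreline[, 2] - s$center[2])^2
      anchor <- centreline[which.min(d2), ]
      nm <- band_mask(shape, s$center, anchor, nw)
      neck_masks[[si]] <- nm & !spine_masks[[si]] & !dend_mask
    } else {
      neck_masks[[si]] <- matrix(FALSE, shape[1], shape[2])
    }
    spine_centers[[si]] <- s$center
  }

  base_frame <- function(ch, dshift, wander) {
    img <- matrix(spec$background, shape[1], shape[2])
    put <- function(mask, val, extra = c(0, 0)) {
      total <- dshift + extra
      m <- if (any(total != 0)) shift_matrix(mask, total[1], total[2], fill = FALSE) else mask
      img[m] <<- pmax(img[m], val)
    }
    if (!is.null(spec$dendrite) && ch == (spec$dendrite$channel %||% 1)) {
      put(dend_mask, spec$dendrite$intensity)
    }
    for (si in seq_along(spec$spines)) {
      s <- spec$spines[[si]]
      if (ch != (s$channel %||% 1)) next
      w <- wander[[si]]
      put(spine_masks[[si]], s$intensity, w)
      if (any(neck_masks[[si]])) {
        put(neck_masks[[si]], s$neck_intensity %||% s$intensity, w)
      }
    }
    for (p in spec$puncta) {
      if (ch != (p$channel %||% 1)) next
      ctr <- p$center + dshift
      rad <- ceiling(4 * p$sigma)
      r0 <- max(1, floor(ctr[1]) - rad); r1 <- min(shape[1], ceiling(ctr[1]) + rad)
      c0 <- max(1, floor(ctr[2]) - rad); c1 <- min(shape[2], ceiling(ctr[2]) + rad)
      if (r1 < r0 || c1 < c0) next
      rr <- r0:r1; cc <- c0:c1
      d2 <- outer((rr - ctr[1])^2, (cc - ctr[2])^2, "+")
      img[rr, cc] <- img[rr, cc] + p$amplitude * exp(-d2 / (2 * p$sigma^2))
    }
    img
  }

  data <- array(0, dim = c(tt, nch, shape[1], shape[2]))
  sd_g <- spec$noise$gaussian_sd %||% 0
  spd <- spec$noise$sp_density %||% 0
  unclamped11 <- NULL  # first frame/channel before clamping, for SNR readout
  for (t in seq_len(tt)) {
    wander <- lapply(spec$spines, function(s) {
      if (is.null(s$wander)) c(0, 0) else s$wander[t, ]
    })
    for (ch in seq_len(nch)) {
      img <- base_frame(ch, drift[t, ], wander)
      if (sd_g > 0) img <- img + rnorm(length(img), 0, sd_g)
      if (t == 1 && ch == 1) unclamped11 <- img
      if (spd > 0) {
        npix <- length(img)
        nsp <- round(spd * npix)
        if (nsp > 0) {
          idx <- sample.int(npix, nsp)
          half <- nsp %/% 2
          amp <- spec$noise$sp_amplitude %||% (max(img) * 1.5)
          img[idx[seq_len(half)]] <- amp
          if (nsp > half) img[idx[(half + 1):nsp]] <- 0
        }
      }
      data[t, ch, , ] <- round(pmax(img, 0))
    }
  }
  stack <- image_stack(data, pixel_size = spec$pixel_size)

  structure_mask <- dend_mask
  for (m in spine_masks) structure_mask <- structure_mask | m
  # SNR measured on the pre-clamping frame: clamping negative excursions to
  # zero at low SNR would otherwise bias the background mean upward
  snr <- NA_real_
  if (any(structure_mask) && sd_g > 0) {
    snr <- (mean(unclamped11[structure_mask]) -
            mean(unclamped11[!structure_mask])) / sd_g
  }
  truth <- list(
    dendrite_mask = dend_mask,
    centreline = centreline,
    width = if (!is.null(spec$dendrite)) spec$dendrite$width else NULL,
    spine_masks = spine_masks,
    spine_centers = spine_centers,
    neck_masks = neck_masks,
    puncta = spec$puncta,
    shifts = drift,
    snr = snr,
    structure_mask = structure_mask
  )
  list(stack = stack, truth = truth, spec = spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian noise SD that realizes a target plateau SNR.
noise_for_snr <- function(intensity, background, snr) (intensity - background) / snr

#' The canonical fixture gallery
#'
#' A named collection of ground-truthed synthetic scenes exercising every
#' pipeline stage: straight and curved tubes, a tube carrying six spines
#' spanning all four morphological classes, a crowded spine pair 6 px
#' apart, a puncta field with a soma polygon and a dendrite, a drifting
#' 5-frame series, and an SNR ladder at 0.5, 1, 2, 3 and 5. Defaults model
#' a typical confocal setup: 0.1 um/px, a 10 px (1 um) wide dendrite, and
#' plateau intensities of 300 over a background of 20.
#'
#' @param seed base RNG seed.
#' @param snr signal-to-noise ratio of the non-ladder scenes.
#' @return named list of rendered fixtures (`stack`, `truth`, `spec`).
#' @export
fixture_gallery <- function(seed = 1, snr = 5) {
  bg <- 20; int <- 300
  sdg <- noise_for_snr(int, bg, snr)
  gal <- list()

  gal$straight_tube <- render_fixture(fixture_spec(
    shape = c(120, 200), background = bg,
    dendrite = list(points = rbind(c(60, 15), c(60, 185)), width = 10, intensity = int),
    noise = list(gaussian_sd = sdg), seed = seed
  ))

  gal$curved_tube <- render_fixture(fixture_spec(
    shape = c(140, 200), background = bg,
    dendrite = list(points = rbind(c(110, 15), c(80, 60), c(40, 100), c(60, 150), c(100, 185)),
                    width = 10, intensity = int),
    noise = list(gaussian_sd = sdg), seed = seed + 1
  ))

  # six spines spanning stubby / mushroom / thin / outlier
  mk_spine <- function(center, radius, neck_length, neck_width) {
    list(center = center, radius = radius, intensity = int,
         neck_length = neck_length, neck_width = neck_width)
  }
  gal$four_class_spines <- render_fixture(fixture_spec(
    shape = c(120, 240), background = bg,
    dendrite = list(points = rbind(c(60, 15), c(60, 225)), width = 10, intensity = int),
    spines = list(
      mk_spine(c(52, 40), 6, 0, 0),       # stubby: flush with the shaft, no neck
      mk_spine(c(40, 80), 7, 10, 3),      # mushroom: big head, thin neck
      mk_spine(c(80, 80), 7, 10, 3),      # mushroom (below the shaft)
      mk_spine(c(40, 130), 5, 10, 5),     # thin
      mk_spine(c(82, 140), 5, 12, 6),     # thin
      mk_spine(c(38, 190), 4, 12, 10)     # outlier: neck wider than head
    ),
    noise = list(gaussian_sd = sdg), seed = seed + 2
  ))

  gal$crowded_pair <- render_fixture(fixture_spec(
    shape = c(100, 120), background = bg,
    dendrite = list(points = rbind(c(70, 10), c(70, 110)), width = 10, intensity = int),
    spines = list(mk_spine(c(45, 57), 5, 8, 3), mk_spine(c(45, 63), 5, 8, 3)),
    noise = list(gaussian_sd = sdg), seed = seed + 3
  ))

  gal$puncta_field <- puncta_count_fixture(8, seed = seed + 4,
                                           n_dendrite_puncta = 5)

  wander <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2), c(0, 0))
  gal$drifting_series <- render_fixture(fixture_spec(
    shape = c(110, 160), background = bg,
    dendrite = list(points = rbind(c(60, 15), c(60, 145)), width = 10, intensity = int),
    spines = list(
      c(mk_spine(c(42, 60), 6, 8, 3), list(wander = wander)),
      mk_spine(c(42, 110), 6, 8, 3)
    ),
    drift = cbind(0:4, 0:4),
    noise = list(gaussian_sd = sdg), n_time = 5, seed = seed + 5
  ))

  gal$snr_ladder <- lapply(c(0.5, 1, 2, 3, 5), function(s) {
    render_fixture(fixture_spec(
      shape = c(110, 180), background = bg,
      dendrite = list(points = rbind(c(60, 15), c(60, 165)), width = 10, intensity = int),
      spines = list(mk_spine(c(42, 60), 6, 8, 3), mk_spine(c(80, 100), 6, 8, 3),
                    mk_spine(c(42, 140), 6, 8, 3)),
      noise = list(gaussian_sd = noise_for_snr(int, bg, s)),
      seed = seed + 6
    ))
  })
  names(gal$snr_ladder) <- paste0("snr_", c("0.5", "1", "2", "3", "5"))
  gal
}

#' Puncta counting fixture with well-separated blobs
#'
#' A soma polygon containing `n` Gaussian puncta on a deterministic jittered
#' grid, plus an optional dendrite tube carrying further puncta. Blob
#' amplitude is 400 with sigma 2.5 px; Gaussian noise SD is amplitude/10,
#' a typical smFISH contrast.
#'
#' @param n number of puncta inside the soma polygon.
#' @param seed RNG seed.
#' @param n_dendrite_puncta puncta seeded along the dendrite axis.
#' @return a rendered fixture; `truth$soma_roi` holds the soma polygon and
#'   `truth$puncta` the ground-truth blob list.
#' @export
puncta_count_fixture <- function(n, seed = 1, n_dendrite_puncta = 0) {
  amp <- 400; sig <- 2.5; bg <- 20
  shape <- c(220, 260)
  soma <- roi_polygon(rbind(c(20, 20), c(20, 180), c(180, 180), c(180, 20)))
  # deterministic jittered grid inside the soma, >= 6 sigma separation
  k <- ceiling(sqrt(n))
  rows <- seq(35, 165, length.out = k)
  cols <- seq(35, 165, length.out = k)
  grid <- as.matrix(expand.grid(row = rows, col = cols))[seq_len(n), , drop = FALSE]
  set.seed(seed)
  grid <- grid + matrix(runif(2 * n, -2, 2), n, 2)
  puncta <- lapply(seq_len(n), function(i) {
    list(center = grid[i, ], sigma = sig, amplitude = amp, compartment = "soma")
  })
  dendrite <- NULL
  if (n_dendrite_puncta > 0) {
    dendrite <- list(points = rbind(c(205, 15), c(205, 245)), width = 10,
                     intensity = 120)
    dcols <- seq(35, 225, length.out = n_dendrite_puncta)
    puncta <- c(puncta, lapply(seq_len(n_dendrite_puncta), function(i) {
      list(center = c(205, dcols[i]), sigma = sig, amplitude = amp,
           compartment = "neurite")
    }))
  }
  fx <- render_fixture(fixture_spec(
    shape = shape, background = bg, dendrite = dendrite, puncta = puncta,
    noise = list(gaussian_sd = amp / 10), seed = seed
  ))
  fx$truth$soma_roi <- soma
  fx
}

#' Materialize the fixture gallery to disk
#'
#' Writes each gallery scene as a 16-bit TIFF plus ground-truth CSV tables
#' and PNG masks, for inspection or use outside R.
#'
#' @param out_dir output directory.
#' @param seed passed to [fixture_gallery()].
#' @return invisibly, the output directory.
#' @export
write_gallery <- function(out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gal <- fixture_gallery(seed = seed)
  flat <- list()
  for (nm in names(gal)) {
    if (nm == "snr_ladder") {
      for (k in names(gal$snr_ladder)) flat[[paste0("ladder_", k)]] <- gal$snr_ladder[[k]]
    } else flat[[nm]] <- gal[[nm]]
  }
  for (nm in names(flat)) {
    fx <- flat[[nm]]
    write_stack(fx$stack, file.path(out_dir, paste0(nm, ".tif")))
    if (!is.null(fx$truth$centreline)) {
      write.csv(as.data.frame(fx$truth$centreline),
                file.path(out_dir, paste0(nm, "_centreline.csv")), row.names = FALSE)
      write_mask_png(fx$truth$dendrite_mask,
                     file.path(out_dir, paste0(nm, "_dendrite_mask.png")))
    }
  }
  invisible(out_dir)
}
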