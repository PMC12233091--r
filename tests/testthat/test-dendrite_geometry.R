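test_that("edge detection finds band borders and nothing on constant input", {
  expect_false(any(detect_edges(matrix(7, 30, 30), 1, 3)))
  img <- band_image(c(30, 60), 15, 11)  # band rows 10..20
  e <- detect_edges(img, 1, 3)
  rows <- sort(unique(which(e, arr.ind = TRUE)[, 1]))
  expect_true(all(abs(rows - 9.5) <= 1.5 | abs(rows - 20.5) <= 1.5))
  expect_true(any(rows < 15) && any(rows > 15))
})

test_that("edge count is non-increasing in the smoothing scale beyond the noise scale", {
  set.seed(5)
  img <- band_image(c(40, 80), 20, 11) + matrix(abs(rnorm(40 * 80, 0, 40)), 40, 80)
  counts <- vapply(c(1, 2, 3, 4), function(s) sum(detect_edges(img, s, 3)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("ellipse growth recovers band half-widths and survives edge gaps", {
  img <- band_image(c(30, 60), 15, 11)
  e <- detect_edges(img, 1, 3)
  ge <- grow_ellipse(c(15, 30), c(0, 1), e, semi_minor = 2, max_semi_major = 20)
  expect_true(abs(ge$left - 5) <= 1 && abs(ge$right - 5) <= 1)
  expect_false(ge$flag_left || ge$flag_right)
  # a 1-px gap in the edge right on the normal: the arc still terminates
  e_gap <- e
  e_gap[, 30] <- FALSE  # remove edge pixels in the probe column
  ge2 <- grow_ellipse(c(15, 30), c(0, 1), e_gap, semi_minor = 2, max_semi_major = 20)
  expect_false(ge2$flag_left || ge2$flag_right)
  expect_true(abs(ge2$left - 5) <= 2 && abs(ge2$right - 5) <= 2)
  # no edges at all: capped and flagged
  ge3 <- grow_ellipse(c(15, 30), c(0, 1), e & FALSE, semi_minor = 2, max_semi_major = 12)
  expect_equal(c(ge3$left, ge3$right), c(12, 12))
  expect_true(ge3$flag_left && ge3$flag_right)
})

test_that("width profiles are flat on clean tubes and spikes are smoothed away", {
  img <- band_image(c(40, 120), 20, 11)
  bm <- suppressWarnings(binarize(img, 1, 100))
  p <- shortest_path(build_cost_field(bm), c(20, 5), c(20, 115))
  e <- detect_edges(img, 1, 3)
  prof <- compute_profile(p, e)
  w <- rowSums(prof$half_widths)
  expect_lte(diff(range(w)), 2)
  expect_false(any(prof$smoothed))
  # add an attached protrusion on the upper edge (band spans rows 15..25)
  img2 <- img
  img2[9:15, 55:61] <- 300  # spine footprint pushes the upper edge out
  e2 <- detect_edges(img2, 1, 3)
  prof_s <- compute_profile(p, e2, smoothing_strength = 0.3)
  prof_raw <- compute_profile(p, e2, smoothing_strength = Inf)
  expect_true(any(prof_s$smoothed))
  cols <- p$full_rank[, 2]
  off <- cols < 45 | cols > 72
  on_fp <- cols >= 53 & cols <= 63
  w_off <- mean(rowSums(prof_raw$half_widths[off, ]))
  # the raw profile spikes over the footprint; smoothing restores continuity
  expect_gt(max(rowSums(prof_raw$half_widths[on_fp, ])), w_off + 2)
  expect_lte(max(abs(rowSums(prof_s$half_widths[on_fp, ]) - w_off)), 1.5)
  # off-footprint widths are untouched by the smoothing condition
  expect_equal(prof_s$half_widths[off, ], prof_raw$half_widths[off, ])
  # flagged points coincide with the protrusion footprint
  flagged_cols <- cols[prof_s$smoothed]
  expect_true(all(flagged_cols >= 48 & flagged_cols <= 72))
  # infinite strength flags nothing
  expect_false(any(prof_raw$smoothed))
})

test_that("the segmentation mask is the union of per-point ellipses containing the path", {
  img <- band_image(c(40, 120), 20, 11)
  bm <- suppressWarnings(binarize(img, 1, 100))
  p <- shortest_path(build_cost_field(bm), c(20, 5), c(20, 115))
  e <- detect_edges(img, 1, 3)
  seg <- build_mask(p, compute_profile(p, e), dim(img))
  expect_true(all(seg$mask[p$full_rank]))
  truth <- img > 100
  m <- evaluate_segmentation(seg$mask, truth)
  expect_gte(sum(seg$mask & truth) / sum(seg$mask | truth), 0.8)  # Jaccard
  expect_gte(m["f1"], 0.9)
  # degenerate profile: zero half-widths collapse the mask onto the path
  prof0 <- compute_profile(p, e)
  prof0$half_widths[] <- 0
  prof0$semi_minor <- 0.4
  seg0 <- build_mask(p, prof0, dim(img))
  expect_equal(which(seg0$mask), which(matrix(seq_along(img), nrow(img)) %in%
                                         ((p$full_rank[, 2] - 1) * nrow(img) + p$full_rank[, 1])))
})

test_that("luminosity along the axis of a constant tube is constant", {
  img <- band_image(c(40, 120), 20, 11)
  stack <- image_stack(img, pixel_size = 0.1)
  bm <- suppressWarnings(binarize(img, 1, 100))
  p <- shortest_path(build_cost_field(bm), c(20, 5), c(20, 115))
  seg <- build_mask(p, compute_profile(p, detect_edges(img, 1, 3)), dim(img), stack)
  expect_equal(diff(range(seg$stats$axis_luminosity[1, 1, ])), 0)
  expect_equal(length(seg$stats$width_um), nrow(p$full_rank))
})

test_that("the straight-chord baseline honours physical units", {
  bl <- straight_baseline(c(20, 10), c(20, 90), 2, 0.2, c(40, 100))
  expect_equal(sort(unique(which(bl, arr.ind = TRUE)[, 1])), 15:25)  # 10 px thick
  # degenerate: single disc
  bl0 <- straight_baseline(c(20, 50), c(20, 50), 2, 0.2, c(40, 100))
  expect_true(sum(bl0) > 0 && sum(bl0) <= pi * 5.5^2)
  expect_error(straight_baseline(c(1, 1), c(2, 2), 2, NULL, c(10, 10)), "pixel_size")
  # 45-degree chord area ~ stadium: length x thickness plus half-disc caps
  bl45 <- straight_baseline(c(10, 10), c(60, 60), 2, 0.1, c(80, 80))
  len <- sqrt(2) * 50
  stadium <- len * 20 + pi * 10^2
  expect_lt(abs(sum(bl45) - stadium) / stadium, 0.08)
})

test_that("segmentation metrics follow the stated conventions", {
  a <- matrix(FALSE, 5, 5); a[2:3, 2:3] <- TRUE
  expect_equal(unname(evaluate_segmentation(a, a)), c(1, 1, 1))
  b <- matrix(FALSE, 5, 5); b[5, 5] <- TRUE
  expect_equal(unname(evaluate_segmentation(a, b)), c(0, 0, 0))
  # precision = recall = 0.5 -> F1 = 0.5 (harmonic mean of equals)
  pred <- matrix(FALSE, 2, 2); pred[1, 1] <- TRUE; pred[1, 2] <- TRUE
  tru <- matrix(FALSE, 2, 2); tru[1, 1] <- TRUE; tru[2, 1] <- TRUE
  expect_equal(unname(evaluate_segmentation(pred, tru)), c(0.5, 0.5, 0.5))
  # empty-mask conventions
  e <- matrix(FALSE, 5, 5)
  expect_equal(unname(evaluate_segmentation(e, e)), c(1, 1, 1))
  expect_equal(unname(evaluate_segmentation(e, a))[1], 0)
  expect_error(evaluate_segmentation(a, matrix(FALSE, 4, 4)), "differ")
})

test_that("width recovery holds across tube widths at SNR 3", {
  for (w in c(6, 10, 16)) {
    fx <- render_fixture(fixture_spec(
      shape = c(70, 140), background = 20,
      dendrite = list(points = rbind(c(35, 10), c(35, 130)), width = w, intensity = 300),
      noise = list(gaussian_sd = (300 - 20) / 3), seed = 30 + w))
    r <- analyse_dendrite(fx, c(35, 10), c(35, 130))
    mae <- mean(abs(rowSums(r$profile$half_widths) - w))
    expect_lte(mae, 1.5)
  }
})

test_that("spine protrusions barely perturb the recovered dendrite width", {
  gal <- get_gallery()
  bare <- analyse_dendrite(gal$straight_tube, c(60, 15), c(60, 185))
  spiny <- analyse_dendrite(gal$four_class_spines, c(60, 15), c(60, 225))
  w_bare <- mean(rowSums(bare$profile$half_widths))
  w_spiny <- mean(rowSums(spiny$profile$half_widths))
  expect_lte(abs(w_spiny - w_bare), 1)
})
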