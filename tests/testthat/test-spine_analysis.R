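test_that("confidence filtering keeps manual centres and respects the threshold", {
  cand <- list(spine_center(5, 5, 0.3), spine_center(6, 6, 0.6),
               spine_center(7, 7, 0.9), spine_center(8, 8, 1))
  expect_length(filter_detections(cand, 0.5), 3)
  expect_length(filter_detections(cand, 0), 4)
  kept <- filter_detections(cand, 1)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$confidence, 1)
  expect_error(spine_center(1, 1, 1.2), "confidence")
})

test_that("ray growth matches the Gaussian isocontour analytically", {
  img <- gaussian_spot(c(61, 61), c(31, 31), sigma = 3, amp = 100)
  roi <- grow_spine_roi(img, c(31, 31),
                        params = spine_params(drop_factor = 0.5, n_break = 1,
                                              filter_size = 1))
  r_expect <- 3 * sqrt(2 * log(2))  # where I falls to half the peak
  radii <- attr(roi, "ray_radii")
  expect_true(all(abs(radii - r_expect) <= 1))
})

test_that("the other-spine rule halts a ray at the bisector", {
  img <- matrix(100, 41, 41)
  roi <- grow_spine_roi(img, c(21, 21), all_centers = list(c(21, 27)),
                        params = spine_params(drop_factor = 0, n_break = 1,
                                              max_extent = 15, filter_size = 1))
  expect_lte(attr(roi, "ray_radii")[3], 3)  # east ray, centres 6 px apart
})

test_that("only the fall-back rule fires on a uniform field", {
  img <- matrix(100, 41, 41)
  roi <- grow_spine_roi(img, c(21, 21),
                        params = spine_params(drop_factor = 0, n_break = 1,
                                              max_extent = 10, filter_size = 1))
  expect_equal(attr(roi, "ray_radii"), rep(10, 8))
  v <- roi$vertices
  ctr <- colMeans(v)
  rad <- sqrt((v[, 1] - ctr[1])^2 + (v[, 2] - ctr[2])^2)
  expect_true(all(abs(rad - 10) <= 1))  # regular octagon up to rounding
})

test_that("the dendrite rule stops rays at the mask", {
  img <- matrix(100, 41, 41)
  dm <- matrix(FALSE, 41, 41); dm[31:41, ] <- TRUE
  roi <- grow_spine_roi(img, c(21, 21), dendrite_mask = dm,
                        params = spine_params(drop_factor = 0, n_break = 1,
                                              max_extent = 15, filter_size = 1))
  expect_lte(attr(roi, "ray_radii")[5], 10)  # south ray stops at row 31
})

test_that("degenerate seeds are rejected", {
  img <- matrix(0, 21, 21); img[11, 11] <- 0
  expect_error(grow_spine_roi(img, c(30, 5)), "outside")
  expect_error(grow_spine_roi(img, c(11, 11), params = spine_params(filter_size = 1)),
               "degenerate seed")
})

test_that("perturbed-seed averaging uses five polygons and respects symmetry", {
  img <- gaussian_spot(c(61, 61), c(31, 31), sigma = 4, amp = 100)
  pars <- spine_params(drop_factor = 0.5, n_break = 1, filter_size = 1)
  avg <- average_perturbed_rois(img, c(31, 31), params = pars)
  expect_equal(attr(avg, "n_averaged"), 5)
  single <- grow_spine_roi(img, c(31, 31), params = pars)
  expect_true(all(abs(avg$vertices - single$vertices) <= 1))
  # corner seed: out-of-bounds perturbations are skipped, not fatal
  img2 <- matrix(100, 30, 30)
  corner <- average_perturbed_rois(img2, c(1, 1),
                                   params = spine_params(drop_factor = 0, n_break = 1,
                                                         max_extent = 5, filter_size = 1))
  expect_lte(attr(corner, "n_averaged"), 3)
  expect_gte(attr(corner, "n_averaged"), 1)
})

test_that("rays are mutually independent and monotone in the drop factor", {
  set.seed(8)
  img <- gaussian_spot(c(61, 61), c(31, 31), sigma = 4, amp = 100) +
    matrix(runif(61 * 61, 0, 5), 61, 61)
  base <- attr(grow_spine_roi(img, c(31, 31),
                              params = spine_params(0.5, 1, 30, 1)), "ray_radii")
  # blocking one direction with another centre never changes the others
  east_blocked <- attr(grow_spine_roi(img, c(31, 31), all_centers = list(c(31, 37)),
                                      params = spine_params(0.5, 1, 30, 1)), "ray_radii")
  expect_true(all(east_blocked[-c(2, 3, 4)] == base[-c(2, 3, 4)]))
  expect_lte(east_blocked[3], base[3])
  # more permissive drop factor never shrinks a ray
  for (df_pair in list(c(0.6, 0.4), c(0.4, 0.2))) {
    r_hi <- attr(grow_spine_roi(img, c(31, 31),
                                params = spine_params(df_pair[1], 1, 30, 1)), "ray_radii")
    r_lo <- attr(grow_spine_roi(img, c(31, 31),
                                params = spine_params(df_pair[2], 1, 30, 1)), "ray_radii")
    expect_true(all(r_lo >= r_hi))
  }
})

test_that("background ROIs land close by without touching occupied pixels", {
  img <- matrix(50, 80, 80)
  spine <- roi_polygon(rbind(c(35, 35), c(35, 45), c(45, 45), c(45, 35)))
  occupied <- rasterize_polygon(spine, c(80, 80))
  bg <- place_background(spine, occupied, c(80, 80))
  expect_false(any(rasterize_polygon(bg, c(80, 80)) & occupied))
  expect_lt(sqrt(sum((polygon_centroid(bg) - polygon_centroid(spine))^2)), 40)
  expect_equal(mean(img[rasterize_polygon(bg, c(80, 80))]), 50)
  # fully occupied frame: unplaceable
  expect_error(place_background(spine, matrix(TRUE, 80, 80), c(80, 80)),
               "no unoccupied")
})

test_that("neck tracing recovers bridge geometry and reports honest absences", {
  # mushroom fixture: disc head connected to tube by a narrow bridge
  fx <- render_fixture(fixture_spec(
    shape = c(80, 100), background = 20,
    dendrite = list(points = rbind(c(50, 10), c(50, 90)), width = 10, intensity = 300),
    spines = list(list(center = c(30, 50), radius = 6, intensity = 300,
                       neck_length = 8, neck_width = 2)),
    noise = list(gaussian_sd = 10), seed = 4))
  f <- get_frame(fx$stack, 1, 1)
  seg <- analyse_dendrite(fx, c(50, 10), c(50, 90))$seg
  head_roi <- average_perturbed_rois(f, c(30, 50), list(c(30, 50)), seg$mask)
  neck <- trace_neck(f, c(30, 50), head_roi, seg)
  expect_s3_class(neck, "spine_neck")
  # head centre to shaft edge is ~15 px; the in-between bridge is 8-9 px
  expect_true(neck$length >= 6 && neck$length <= 17)
  expect_true(neck$neck_width >= 1 && neck$neck_width <= 4)
  # zero pixel overlap with the head ROI
  expect_false(any(neck$mask & rasterize_polygon(head_roi, dim(f))))
  # spine centre inside the dendrite: absence marker, not an error
  flush <- trace_neck(f, c(50, 50), head_roi, seg)
  expect_s3_class(flush, "neck_absent")
})

test_that("classification follows the printed NW/HW rules", {
  expect_equal(classify_spine(0, 10), "stubby")
  expect_equal(classify_spine(3, 10), "mushroom")
  expect_equal(classify_spine(8, 10), "thin")
  expect_equal(classify_spine(12, 10), "outlier")
  # boundary handling: 0.5 and 1.1 belong to 'thin'
  expect_equal(classify_spine(5, 10), "thin")
  expect_equal(classify_spine(11, 10), "thin")
  expect_error(classify_spine(3, 0), "head width")
  expect_error(classify_spine(-1, 5), "neck width")
})

test_that("exactly one label exists for every NW >= 0, HW > 0", {
  grid <- expand.grid(NW = seq(0, 20, by = 0.5), HW = seq(0.5, 15, by = 0.5))
  labs <- mapply(classify_spine, grid$NW, grid$HW)
  expect_true(all(labs %in% c("stubby", "mushroom", "thin", "outlier")))
  expect_equal(length(labs), nrow(grid))
})

test_that("spine statistics follow constant-field and monotone-brightening logic", {
  # constant field: mean equals the constant, background-corrected is 0
  img <- matrix(80, 60, 60)
  stack <- image_stack(img, pixel_size = 0.1)
  ctr <- spine_center(30, 30)
  rec <- make_spine_record(stack, ctr, list(ctr), NULL, mode = "luminosity",
                           params = spine_params(drop_factor = 0, n_break = 1,
                                                 max_extent = 8, filter_size = 1),
                           trace_necks = FALSE)
  rec$background_roi <- translate_roi(rec$head_rois[[1]], 0, 20)
  st <- spine_stats(rec, stack)
  expect_equal(st$mean_luminosity, 80)
  expect_equal(st$corrected_luminosity, 0)
  expect_equal(st$area_um2, st$area_px2 * 0.01)
  # luminosity mode on a brightening series: one fixed ROI, increasing series
  arr <- array(0, dim = c(3, 1, 60, 60))
  for (t in 1:3) arr[t, 1, , ] <- gaussian_spot(c(60, 60), c(30, 30), 4, amp = 50 * t)
  bstack <- image_stack(arr)
  rec2 <- make_spine_record(bstack, ctr, list(ctr), NULL, mode = "luminosity",
                            params = spine_params(0.4, 1, 20, 1), trace_necks = FALSE)
  expect_length(rec2$head_rois, 1)
  st2 <- spine_stats(rec2, bstack)
  expect_true(all(diff(st2$mean_luminosity) > 0))
  # area mode: one ROI per timepoint
  rec3 <- make_spine_record(bstack, ctr, list(ctr), NULL, mode = "area",
                            params = spine_params(0.4, 1, 20, 1), trace_necks = FALSE)
  expect_length(rec3$head_rois, 3)
})

test_that("head ROIs stay accurate on disc ground truth at SNR >= 3", {
  gal <- get_gallery()
  for (rung in c("snr_3", "snr_5")) {
    fx <- gal$snr_ladder[[rung]]
    f <- get_frame(fx$stack, 1, 1)
    seg <- analyse_dendrite(fx, c(60, 15), c(60, 165), filter_size = 7, sigma = 3)$seg
    ctrs <- lapply(fx$truth$spine_centers, function(s) spine_center(s[1], s[2]))
    for (i in seq_along(ctrs)) {
      roi <- average_perturbed_rois(f, ctrs[[i]], ctrs, seg$mask)
      m <- evaluate_segmentation(rasterize_polygon(roi, dim(f)), fx$truth$spine_masks[[i]])
      expect_gte(m["recall"], 0.7)
      expect_gte(m["precision"], 0.7)
    }
  }
})
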