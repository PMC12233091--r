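test_that("binarize thresholds the median-filtered image", {
  # constant image: nothing strictly above the mean
  expect_warning(bm <- binarize(matrix(5, 10, 10), 3, "mean"), "empty mask")
  expect_false(any(bm$mask))
  # bright tube on zero background: mask matches direct pixelwise threshold
  img <- band_image(c(30, 60), 15, 10, intensity = 200, background = 0)
  bm <- binarize(img, 3, "mean")
  oracle <- img > mean(img)  # noiseless: filter is a no-op in the interior
  interior <- matrix(FALSE, 30, 60)
  interior[3:28, 3:58] <- TRUE
  expect_true(all(bm$mask[interior] == oracle[interior]))
  # single salt pixel removed by a 3-px median filter
  salt <- matrix(0, 20, 20); salt[10, 10] <- 1000
  bm2 <- suppressWarnings(binarize(salt, 3, 50))
  expect_false(any(bm2$mask))
})

test_that("the cost field decreases with clearance and walls are impassable", {
  img <- band_image(c(30, 60), 15, 11)
  cf <- build_cost_field(suppressWarnings(binarize(img, 1, 100)))
  expect_true(all(cf$boundary_distance[!cf$admissible] == 0))
  expect_true(all(is.infinite(cf$step_cost[!cf$admissible])))
  # the band spans rows 10..20: maximal clearance on the middle row
  mid <- cf$boundary_distance[15, 30]
  expect_true(all(cf$boundary_distance[c(10, 20), 30] < mid))
  # monotone: step_cost strictly decreasing in boundary distance
  d <- cf$boundary_distance[cf$admissible]
  sc <- cf$step_cost[cf$admissible]
  ord <- order(d)
  expect_true(all(diff(sc[ord][!duplicated(sort(d))]) <= 0))
  expect_error(build_cost_field(matrix(FALSE, 5, 5)), "no dendrite")
})

test_that("boundary distances match a brute-force transform", {
  set.seed(42)
  for (k in 1:5) {
    m <- random_mask(12, 14)
    cf <- build_cost_field(m)
    expect_equal(cf$boundary_distance[m], brute_distance_transform(m)[m],
                 tolerance = 1e-6)
  }
  # all-true mask: distance to the image border
  cf <- build_cost_field(matrix(TRUE, 9, 9))
  expect_equal(cf$boundary_distance[5, 5], 5)
  expect_equal(cf$boundary_distance[1, 5], 1)
})

test_that("the shortest path follows the band centre at maximal clearance", {
  img <- band_image(c(15, 40), 8, 11)
  cf <- build_cost_field(suppressWarnings(binarize(img, 1, 100)))
  p <- shortest_path(cf, c(8, 3), c(8, 38))
  expect_true(all(p$full_rank[, 1] == 8))
  # consecutive pixels are 8-connected
  steps <- abs(diff(p$full_rank))
  expect_true(all(steps <= 1) && all(rowSums(steps) >= 1))
  # endpoints preserved
  expect_equal(unname(p$full_rank[1, ]), c(8, 3))
  expect_equal(unname(p$full_rank[nrow(p$full_rank), ]), c(8, 38))
})

test_that("degenerate and unreachable endpoint cases are handled", {
  img <- band_image(c(15, 40), 8, 5)
  cf <- build_cost_field(suppressWarnings(binarize(img, 1, 100)))
  p <- shortest_path(cf, c(8, 10), c(8, 10))
  expect_equal(nrow(p$full_rank), 1)
  expect_equal(attr(p, "total_cost"), 0)
  # two disconnected blobs
  m <- matrix(FALSE, 20, 20); m[3:5, 3:5] <- TRUE; m[15:17, 15:17] <- TRUE
  cf2 <- build_cost_field(m)
  expect_error(shortest_path(cf2, c(4, 4), c(16, 16)), "different connected components")
  # endpoint snapping within 10 px; error beyond
  p2 <- shortest_path(cf2, c(1, 1), c(5, 5))
  expect_true(m[p2$full_rank[1, 1], p2$full_rank[1, 2]])
  expect_error(shortest_path(build_cost_field(m[1:8, , drop = FALSE]), c(1, 20), c(4, 4)),
               "admissible pixel")
})

test_that("shortest-path cost equals an independent brute-force Dijkstra", {
  set.seed(7)
  n_checked <- 0
  for (k in 1:30) {
    m <- random_mask(15, 15, n_seeds = 2, growth = 80)
    fg <- which(m, arr.ind = TRUE)
    if (nrow(fg) < 2) next
    se <- fg[sample.int(nrow(fg), 2), , drop = FALSE]
    cf <- build_cost_field(m)
    oracle <- brute_dijkstra_cost(m, cf$step_cost, se[1, ], se[2, ])
    got <- tryCatch(attr(shortest_path(cf, se[1, ], se[2, ]), "total_cost"),
                    error = function(e) Inf)
    if (is.finite(oracle)) {
      expect_equal(got, oracle, tolerance = 1e-9)
    } else {
      expect_true(is.infinite(got))
    }
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 25)
})

test_that("an L-corridor path attains the exhaustively enumerated optimum", {
  m <- matrix(FALSE, 8, 8)
  m[2:7, 2:3] <- TRUE   # vertical leg
  m[6:7, 2:7] <- TRUE   # horizontal leg
  cf <- build_cost_field(m)
  got <- attr(shortest_path(cf, c(2, 2), c(7, 7)), "total_cost")
  best <- enumerate_paths_cost(m, cf$step_cost, c(2, 2), c(7, 7))
  expect_equal(got, best, tolerance = 1e-9)
})

test_that("compression keeps only the turning points", {
  straight <- cbind(5, 1:100)
  expect_equal(nrow(compress_path(straight, 2)), 2)
  lpath <- rbind(cbind(1:20, 1), cbind(20, 2:20))
  cp <- compress_path(lpath, 0.5)
  expect_equal(nrow(cp), 3)
  expect_equal(unname(cp[2, ]), c(20, 1))
})

test_that("compress/interpolate round-trips stay within tolerance", {
  set.seed(3)
  for (k in 1:50) {
    # random monotone staircase
    n <- sample(20:60, 1)
    steps <- cbind(sample(0:1, n, replace = TRUE), sample(0:1, n, replace = TRUE))
    steps[rowSums(steps) == 0, 1] <- 1
    chain <- apply(rbind(c(5, 5), steps), 2, cumsum)
    tol <- sample(c(1, 2), 1)
    cp <- compress_path(chain, tol)
    expect_lte(max(synaptrace:::pt_polyline_dist(chain, cp)), tol)
    # rasterized interpolation is 8-connected and within 1 px Hausdorff
    rec <- interpolate_path(cp)
    expect_true(all(abs(diff(rec)) <= 1))
    expect_lte(max(synaptrace:::pt_polyline_dist(rec, chain)), tol + 1)
  }
})

test_that("interpolation rasterizes straight and diagonal segments exactly", {
  expect_equal(nrow(interpolate_path(rbind(c(1, 1), c(1, 10)))), 10)
  diag <- interpolate_path(rbind(c(1, 1), c(6, 6)))
  expect_equal(nrow(diag), 6)
  expect_equal(diag[, 1], diag[, 2])
  expect_error(interpolate_path(rbind(c(1, 1))), "at least 2")
})

test_that("downsampling triggers above 512 px and stays near the full-resolution path", {
  fx <- render_fixture(fixture_spec(
    shape = c(600, 600),
    dendrite = list(points = rbind(c(300, 20), c(300, 580)), width = 12, intensity = 300),
    noise = list(gaussian_sd = 0), seed = 3))
  f <- get_frame(fx$stack, 1, 1)
  cf <- build_cost_field(binarize(f, 3, "mean"))
  pd <- shortest_path(cf, c(300, 25), c(300, 575))
  expect_equal(pd$source_scale, 2)
  pf <- shortest_path(cf, c(300, 25), c(300, 575), downsample_trigger = Inf)
  expect_equal(pf$source_scale, 1)
  dev <- max(synaptrace:::pt_polyline_dist(pd$full_rank, pf$full_rank))
  expect_lte(dev, 2 * pd$source_scale)
  # no trigger at exactly 512
  m <- matrix(FALSE, 512, 100); m[250:260, ] <- TRUE
  p512 <- shortest_path(build_cost_field(m), c(255, 5), c(255, 95))
  expect_equal(p512$source_scale, 1)
})

test_that("centreline accuracy holds on noisy straight tubes of odd widths", {
  for (w in c(5, 9, 15)) {
    fx <- render_fixture(fixture_spec(
      shape = c(60, 120), background = 20,
      dendrite = list(points = rbind(c(30, 10), c(30, 110)), width = w, intensity = 300),
      noise = list(gaussian_sd = (300 - 20) / 3), seed = 20 + w))
    f <- get_frame(fx$stack, 1, 1)
    cf <- build_cost_field(binarize(f, 5, "mean"))
    p <- shortest_path(cf, c(30, 10), c(30, 110))
    expect_lte(mean(abs(p$full_rank[, 1] - 30)), 1)
  }
})
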