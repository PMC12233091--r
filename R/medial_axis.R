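#' Median-filter an image and threshold it into a binary mask
#'
#' A median filter (window `filter_size` pixels) suppresses salt-and-pepper
#' noise; the filtered image is then thresholded. The default threshold
#' `"mean"` resolves to the mean of the filtered image, so only pixels
#' strictly brighter than average are admissible.
#'
#' @param image 2D numeric matrix of finite, non-negative intensities.
#' @param filter_size odd median-filter window in pixels (1 = no filtering).
#' @param threshold numeric intensity cut-off, or `"mean"`.
#' @return a `binary_mask` object with fields `mask`, `threshold_used`,
#'   `filter_size`. An all-background result triggers a warning condition.
#' @export
binarize <- function(image, filter_size = 5, threshold = "mean") {
  if (!all(is.finite(image))) stopf("image must be finite")
  if (filter_size %% 2 != 1 || filter_size < 1) stopf("filter_size must be odd and >= 1")
  med <- median_filter(image, filter_size)
  thr <- if (identical(threshold, "mean")) mean(med) else as.numeric(threshold)
  mask <- med > thr
  if (!any(mask)) warnf("binarize: empty mask (no pixel above threshold %.4g)", thr)
  structure(list(mask = mask, threshold_used = thr, filter_size = filter_size),
            class = "binary_mask")
}

# Median filter on an arbitrary-range image. EBImage's constant-time median
# filter operates on [0, 1] data, so the image is rescaled around the call.
median_filter <- function(image, filter_size) {
  if (filter_size <= 1) return(image)
  rng <- range(image)
  if (rng[2] == rng[1]) return(image)
  sc <- (image - rng[1]) / (rng[2] - rng[1])
  out <- EBImage::medianFilter(sc, size = (filter_size - 1) / 2)
  out * (rng[2] - rng[1]) + rng[1]
}

#' Build the boundary-distance-weighted cost field
#'
#' A shortest path computed on the raw binary mask hugs the dendrite edges,
#' so the admissible region is augmented with the Euclidean distance of each
#' pixel to the nearest inadmissible pixel (image borders count as
#' inadmissible). Traversal cost decreases monotonically with that
#' clearance: `step_cost = 1 / (1 + d)` on admissible pixels and infinite on
#' walls, which pulls the optimal path onto the centreline while keeping all
#' costs positive as Dijkstra requires.
#'
#' @param mask a `binary_mask` from [binarize()] or a logical matrix.
#' @return a `cost_field` with fields `admissible`, `boundary_distance`,
#'   `step_cost`.
#' @export
build_cost_field <- function(mask) {
  m <- if (inherits(mask, "binary_mask")) mask$mask else mask
  if (!any(m)) stopf("no dendrite: the binary mask has no foreground pixel")
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  d <- EBImage::distmap(pad)[2:(nr + 1), 2:(nc + 1)]
  d[!m] <- 0
  sc <- matrix(Inf, nr, nc)
  sc[m] <- 1 / (1 + d[m])
  structure(list(admissible = m, boundary_distance = d, step_cost = sc),
            class = "cost_field")
}

# Snap a point to the nearest admissible pixel within `radius`
# (lexicographic (row, col) tie-break); error beyond the radius.
snap_to_admissible <- function(field, p, radius = 10) {
  p <- round(p)
  nr <- nrow(field$admissible); nc <- ncol(field$admissible)
  if (p[1] >= 1 && p[1] <= nr && p[2] >= 1 && p[2] <= nc && field$admissible[p[1], p[2]]) {
    return(as.integer(p))
  }
  r0 <- max(1, p[1] - radius); r1 <- min(nr, p[1] + radius)
  c0 <- max(1, p[2] - radius); c1 <- min(nc, p[2] + radius)
  sub <- field$admissible[r0:r1, c0:c1, drop = FALSE]
  if (!any(sub)) {
    stopf("point (%d, %d) is not on the dendrite and no admissible pixel lies within %d px",
          p[1], p[2], radius)
  }
  idx <- which(sub, arr.ind = TRUE)
  cand <- cbind(idx[, 1] + r0 - 1, idx[, 2] + c0 - 1)
  d2 <- (cand[, 1] - p[1])^2 + (cand[, 2] - p[2])^2
  ord <- order(d2, cand[, 1], cand[, 2])
  best <- cand[ord[1], ]
  if (sqrt(d2[ord[1]]) > radius) {
    stopf("point (%d, %d): nearest admissible pixel is farther than %d px", p[1], p[2], radius)
  }
  as.integer(best)
}

# Dijkstra over the 8-connected admissible lattice. Orthogonal moves cost
# the mean endpoint step_cost; diagonal moves sqrt(2) times that.
dijkstra_grid <- function(field, start, end) {
  adm <- field$admissible
  nr <- nrow(adm); nc <- ncol(adm)
  cost <- field$step_cost
  lin <- which(adm)
  id <- matrix(NA_integer_, nr, nc)
  id[lin] <- seq_along(lin)
  rows <- ((lin - 1) %% nr) + 1
  cols <- ((lin - 1) %/% nr) + 1
  edges_from <- integer(0); edges_to <- integer(0); wts <- numeric(0)
  # offsets covering each undirected edge once
  offs <- list(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)), c(-1, 1, sqrt(2)))
  for (o in offs) {
    nrw <- rows + o[1]; ncl <- cols + o[2]
    ok <- nrw >= 1 & nrw <= nr & ncl >= 1 & ncl <= nc
    if (!any(ok)) next
    nlin <- (ncl[ok] - 1) * nr + nrw[ok]
    nid <- id[nlin]
    keep <- !is.na(nid)
    if (!any(keep)) next
    f <- id[lin[ok]][keep]
    t <- nid[keep]
    w <- o[3] * (cost[lin[ok]][keep] + cost[nlin[keep]]) / 2
    edges_from <- c(edges_from, f); edges_to <- c(edges_to, t); wts <- c(wts, w)
  }
  g <- igraph::make_empty_graph(n = length(lin), directed = FALSE)
  g <- igraph::add_edges(g, as.vector(rbind(edges_from, edges_to)))
  s <- id[start[1], start[2]]; e <- id[end[1], end[2]]
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = s, to = e, weights = wts, output = "vpath")
  )
  vp <- sp$vpath[[1]]
  if (length(vp) == 0) {
    stopf("no admissible path: (%d, %d) and (%d, %d) lie in different connected components",
          start[1], start[2], end[1], end[2])
  }
  v <- as.integer(vp)
  chain <- cbind(rows[v], cols[v])
  total <- igraph::distances(g, v = s, to = e, weights = wts)[1, 1]
  list(chain = chain, cost = total)
}

# Block-mean downsampling of a logical mask; a block is foreground when at
# least half its pixels are.
pool_mask <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  nr2 <- ceiling(nr / k); nc2 <- ceiling(nc / k)
  pad <- matrix(0, nr2 * k, nc2 * k)
  pad[1:nr, 1:nc] <- m
  dim(pad) <- c(k, nr2, k, nc2)
  means <- apply(pad, c(2, 4), mean)
  means >= 0.5
}

#' Shortest medial-axis path between two endpoints
#'
#' Runs Dijkstra on the 8-connected admissible lattice with
#' boundary-distance-derived step costs, so the optimal path follows the
#' dendrite centreline. Endpoints falling off the admissible region are
#' snapped to the nearest admissible pixel within 10 px. When either image
#' dimension exceeds `downsample_trigger` (default 512), the mask is
#' block-mean pooled by the smallest integer factor that brings it within
#' the trigger, a coarse path is found, and the full-resolution search is
#' re-run inside a corridor around the upscaled coarse path; the result
#' always lies on full-resolution admissible pixels.
#'
#' @param field a `cost_field` from [build_cost_field()].
#' @param start,end `(row, col)` endpoints.
#' @param downsample_trigger image dimension above which pooling engages;
#'   `Inf` disables downsampling.
#' @param tolerance Douglas-Peucker tolerance (px) for control-point
#'   compression of the returned path.
#' @return a `medial_axis_path` with fields `control_points`, `full_rank`
#'   (8-connected pixel chain), `source_scale`; attribute `total_cost`.
#' @export
shortest_path <- function(field, start, end, downsample_trigger = 512, tolerance = 2) {
  start <- snap_to_admissible(field, start)
  end <- snap_to_admissible(field, end)
  if (all(start == end)) {
    p <- matrix(start, 1, 2)
    out <- structure(list(control_points = p, full_rank = p, source_scale = 1L),
                     class = "medial_axis_path")
    attr(out, "total_cost") <- 0
    return(out)
  }
  nr <- nrow(field$admissible); nc <- ncol(field$admissible)
  scale <- 1L
  search_field <- field
  if (max(nr, nc) > downsample_trigger) {
    scale <- as.integer(ceiling(max(nr, nc) / downsample_trigger))
    coarse_mask <- pool_mask(field$admissible, scale)
    coarse <- build_cost_field(coarse_mask)
    cs <- snap_to_admissible(coarse, ceiling(start / scale))
    ce <- snap_to_admissible(coarse, ceiling(end / scale))
    coarse_res <- dijkstra_grid(coarse, cs, ce)
    # corridor: full-res pixels within 2*scale (Chebyshev) of the upscaled path
    up <- (coarse_res$chain - 1) * scale + (scale + 1) / 2
    corridor <- matrix(FALSE, nr, nc)
    half <- 2L * scale
    marks <- rbind(round(up), matrix(start, 1, 2), matrix(end, 1, 2))
    for (i in seq_len(nrow(marks))) {
      r0 <- max(1, marks[i, 1] - half); r1 <- min(nr, marks[i, 1] + half)
      c0 <- max(1, marks[i, 2] - half); c1 <- min(nc, marks[i, 2] + half)
      corridor[r0:r1, c0:c1] <- TRUE
    }
    search_field <- field
    search_field$admissible <- field$admissible & corridor
    search_field$step_cost[!search_field$admissible] <- Inf
  }
  res <- dijkstra_grid(search_field, start, end)
  cp <- compress_path(res$chain, tolerance = tolerance)
  out <- structure(list(control_points = cp, full_rank = res$chain,
                        source_scale = scale),
                   class = "medial_axis_path")
  attr(out, "total_cost") <- res$cost
  out
}

#' Compress a pixel chain to control points (Douglas-Peucker)
#'
#' Retains the major turning points of the path: the smallest subsequence
#' (always including both endpoints) found by recursive Douglas-Peucker
#' splitting such that linear interpolation between the retained points
#' deviates from the original chain by at most `tolerance` pixels.
#'
#' @param full_rank `(n x 2)` pixel chain.
#' @param tolerance maximum perpendicular deviation in pixels.
#' @return `(k x 2)` matrix of control points.
#' @export
compress_path <- function(full_rank, tolerance = 2) {
  pts <- as.matrix(full_rank)
  n <- nrow(pts)
  if (n <= 2) return(pts)
  keep <- rep(FALSE, n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack) > 0) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2) next
    mid <- (i + 1):(j - 1)
    d <- pt_seg_dist(pts[mid, , drop = FALSE], pts[i, ], pts[j, ])
    k <- which.max(d)
    if (d[k] > tolerance) {
      split <- mid[k]
      keep[split] <- TRUE
      stack <- c(stack, list(c(i, split)), list(c(split, j)))
    }
  }
  pts[keep, , drop = FALSE]
}

#' Recover a full-rank pixel chain from control points
#'
#' Rasterizes the polyline through the control points (Bresenham per
#' segment) into an 8-connected pixel chain with no duplicated consecutive
#' pixels.
#'
#' @param control_points `(k x 2)` matrix, `k >= 2`.
#' @return `(n x 2)` integer pixel chain.
#' @export
interpolate_path <- function(control_points) {
  cp <- as.matrix(control_points)
  if (nrow(cp) < 2) stopf("interpolate_path needs at least 2 control points")
  segs <- lapply(seq_len(nrow(cp) - 1), function(i) {
    s <- bresenham(cp[i, ], cp[i + 1, ])
    if (i > 1) s[-1, , drop = FALSE] else s
  })
  chain <- do.call(rbind, segs)
  # drop any residual consecutive duplicates
  if (nrow(chain) > 1) {
    dup <- c(FALSE, rowSums(abs(diff(chain))) == 0)
    chain <- chain[!dup, , drop = FALSE]
  }
  chain
}

# Maximum deviation of a pixel chain from the polyline through control points.
path_deviation <- function(full_rank, control_points) {
  max(pt_polyline_dist(as.matrix(full_rank), as.matrix(control_points)))
}
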