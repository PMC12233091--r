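#' Polygonal and segmented-line regions of interest
#'
#' ROIs use the internal pixel convention everywhere: `(row, col)`
#' coordinates, 1-based, with pixel centres at integer coordinates.
#' Conversion to the 0-based x/y convention of ImageJ happens only at the
#' `.roi` file boundary (see [export_roi()]).
#'
#' @param vertices an `(n x 2)` matrix of `(row, col)` vertices, `n >= 3`.
#'   The polygon is closed implicitly and must be simple
#'   (non-self-intersecting) on creation.
#' @return a `roi_polygon` object.
#' @export
roi_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2) stopf("vertices must be an (n x 2) matrix of (row, col)")
  # collapse consecutive duplicates (closed ring)
  n <- nrow(vertices)
  keep <- c(TRUE, rowSums(abs(vertices[-1, , drop = FALSE] -
                              vertices[-n, , drop = FALSE])) > 1e-9)
  vertices <- vertices[keep, , drop = FALSE]
  n <- nrow(vertices)
  if (n >= 2 && all(abs(vertices[n, ] - vertices[1, ]) < 1e-9)) {
    vertices <- vertices[-n, , drop = FALSE]
    n <- n - 1
  }
  if (n < 3) stopf("a polygon ROI needs at least 3 distinct vertices, got %d", n)
  if (polygon_self_intersects(vertices)) stopf("polygon is self-intersecting")
  structure(list(vertices = vertices), class = "roi_polygon")
}

#' @param points an `(n x 2)` matrix of `(row, col)` control points, `n >= 2`.
#' @param widths optional per-point half-widths in pixels (length `n`, >= 0).
#' @return a `segmented_line` object.
#' @rdname roi_polygon
#' @export
segmented_line <- function(points, widths = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 2 || nrow(points) < 2) {
    stopf("a segmented line needs an (n x 2) matrix with n >= 2 points")
  }
  if (!is.null(widths)) {
    if (length(widths) != nrow(points)) stopf("widths must match the point count")
    if (any(widths < 0)) stopf("widths must be >= 0")
  }
  structure(list(points = points, widths = widths), class = "segmented_line")
}

# Proper-crossing test between segments a1-a2 and b1-b2 (shared endpoints and
# collinear touching do not count: star-shaped octagons must validate).
segments_cross <- function(a1, a2, b1, b2) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(b1, b2, a1); d2 <- d(b1, b2, a2)
  d3 <- d(a1, a2, b1); d4 <- d(a1, a2, b2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

polygon_self_intersects <- function(v) {
  n <- nrow(v)
  if (n <= 3) return(FALSE)
  idx <- rbind(cbind(seq_len(n), c(seq_len(n)[-1], 1)))
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through closure
      if (segments_cross(v[idx[i, 1], ], v[idx[i, 2], ],
                         v[idx[j, 1], ], v[idx[j, 2], ])) return(TRUE)
    }
  }
  FALSE
}

#' Polygon area by the shoelace formula
#' @param roi a `roi_polygon`.
#' @return area in square pixels.
#' @export
polygon_area <- function(roi) {
  v <- roi$vertices
  n <- nrow(v)
  j <- c(seq_len(n)[-1], 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

polygon_centroid <- function(roi) colMeans(roi$vertices)

polygon_circumradius <- function(roi) {
  ctr <- polygon_centroid(roi)
  max(sqrt((roi$vertices[, 1] - ctr[1])^2 + (roi$vertices[, 2] - ctr[2])^2))
}

#' Translate an ROI by an integer or fractional pixel offset
#' @param roi a `roi_polygon` or `segmented_line`.
#' @param drow,dcol offsets in pixels.
#' @return the translated ROI (same class).
#' @export
translate_roi <- function(roi, drow, dcol) {
  if (inherits(roi, "roi_polygon")) {
    roi$vertices[, 1] <- roi$vertices[, 1] + drow
    roi$vertices[, 2] <- roi$vertices[, 2] + dcol
  } else {
    roi$points[, 1] <- roi$points[, 1] + drow
    roi$points[, 2] <- roi$points[, 2] + dcol
  }
  roi
}

#' Even-odd point-in-polygon test
#'
#' Points exactly on the boundary count as inside, so border pixel centres
#' are attributed deterministically.
#'
#' @param points `(n x 2)` matrix of `(row, col)` query points.
#' @param roi a `roi_polygon` (or raw vertex matrix).
#' @return logical vector of length `n`.
#' @export
points_in_polygon <- function(points, roi) {
  v <- if (inherits(roi, "roi_polygon")) roi$vertices else as.matrix(roi)
  points <- matrix(as.numeric(points), ncol = 2)
  n <- nrow(v)
  px <- points[, 1]; py <- points[, 2]
  inside <- rep(FALSE, nrow(points))
  onedge <- rep(FALSE, nrow(points))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    # boundary check: point within 1e-9 of the segment
    dseg <- pt_seg_dist(points, c(xi, yi), c(xj, yj))
    onedge <- onedge | dseg < 1e-9
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside | onedge
}

#' Rasterize a polygon ROI to a logical pixel mask
#'
#' @param roi a `roi_polygon`.
#' @param shape `c(nrow, ncol)` of the target image.
#' @return a logical matrix; `TRUE` where the pixel centre lies inside (or
#'   on the border of) the polygon.
#' @export
rasterize_polygon <- function(roi, shape) {
  v <- roi$vertices
  r0 <- max(1L, floor(min(v[, 1]))); r1 <- min(shape[1], ceiling(max(v[, 1])))
  c0 <- max(1L, floor(min(v[, 2]))); c1 <- min(shape[2], ceiling(max(v[, 2])))
  out <- matrix(FALSE, shape[1], shape[2])
  if (r1 < r0 || c1 < c0) return(out)
  grid <- as.matrix(expand.grid(row = r0:r1, col = c0:c1))
  ins <- points_in_polygon(grid, roi)
  out[grid[ins, , drop = FALSE]] <- TRUE
  out
}

#' Edit polygon vertices
#'
#' Generated ROIs are editable: vertices can be moved, inserted or deleted.
#' Every edit re-validates the polygon invariants.
#'
#' @param roi a `roi_polygon`.
#' @param i vertex index.
#' @param point new `(row, col)` position.
#' @return the edited `roi_polygon`.
#' @export
move_vertex <- function(roi, i, point) {
  v <- roi$vertices
  if (i < 1 || i > nrow(v)) stopf("vertex index %d out of range", i)
  v[i, ] <- point
  roi_polygon(v)
}

#' @rdname move_vertex
#' @export
insert_vertex <- function(roi, i, point) {
  v <- roi$vertices
  if (i < 1 || i > nrow(v) + 1) stopf("vertex index %d out of range", i)
  roi_polygon(rbind(v[seq_len(i - 1), , drop = FALSE], point,
                    v[seq(i, length.out = nrow(v) - i + 1), , drop = FALSE]))
}

#' @rdname move_vertex
#' @export
delete_vertex <- function(roi, i) {
  v <- roi$vertices
  if (i < 1 || i > nrow(v)) stopf("vertex index %d out of range", i)
  roi_polygon(v[-i, , drop = FALSE])
}
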