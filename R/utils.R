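# Internal geometry and raster helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Squared Euclidean distance between point sets (n x 2) and (m x 2).
cross_dist2 <- function(a, b) {
  outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
}

# Distance from points (n x 2) to the segment p-q (each length-2).
pt_seg_dist <- function(pts, p, q) {
  v <- q - p
  len2 <- sum(v^2)
  if (len2 == 0) {
    return(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2))
  }
  t <- ((pts[, 1] - p[1]) * v[1] + (pts[, 2] - p[2]) * v[2]) / len2
  t <- clamp(t, 0, 1)
  sqrt((pts[, 1] - (p[1] + t * v[1]))^2 + (pts[, 2] - (p[2] + t * v[2]))^2)
}

# Minimum distance from each point to a polyline given as an (k x 2) matrix.
pt_polyline_dist <- function(pts, line) {
  if (nrow(line) == 1) {
    return(sqrt((pts[, 1] - line[1, 1])^2 + (pts[, 2] - line[1, 2])^2))
  }
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(line) - 1)) {
    d <- pmin(d, pt_seg_dist(pts, line[i, ], line[i + 1, ]))
  }
  d
}

# Integer raster line between two pixel coordinates (Bresenham, all octants).
# Returns an (n x 2) matrix of (row, col) including both endpoints.
bresenham <- function(p, q) {
  p <- round(p); q <- round(q)
  dr <- abs(q[1] - p[1]); dc <- abs(q[2] - p[2])
  sr <- sign(q[1] - p[1]); sc <- sign(q[2] - p[2])
  n <- max(dr, dc) + 1
  out <- matrix(0L, n, 2)
  r <- p[1]; cc <- p[2]
  err <- dr - dc
  for (i in seq_len(n)) {
    out[i, ] <- c(r, cc)
    if (r == q[1] && cc == q[2]) return(out[seq_len(i), , drop = FALSE])
    e2 <- 2 * err
    if (e2 > -dc) { err <- err - dc; r <- r + sr }
    if (e2 < dr)  { err <- err + dr; cc <- cc + sc }
  }
  out
}

# Shift a matrix by integer (dr, dc), filling exposed pixels with `fill`.
shift_matrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  if (any(ok_r) && any(ok_c)) {
    out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  }
  out
}

# Cumulative arclength along an (n x 2) polyline.
polyline_arclength <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
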