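# Independent oracles, deliberately implemented without the package's own
# graph or image machinery.

# Plain O(V^2) Dijkstra over the 8-connected admissible lattice with the
# same edge-weight convention as the package (mean endpoint step cost,
# sqrt(2) factor on diagonals). Returns the optimal total cost, Inf when
# unreachable.
brute_dijkstra_cost <- function(adm, step_cost, start, end) {
  nr <- nrow(adm); nc <- ncol(adm)
  nodes <- which(adm)
  n <- length(nodes)
  idmap <- matrix(NA_integer_, nr, nc)
  idmap[nodes] <- seq_len(n)
  rows <- ((nodes - 1) %% nr) + 1
  cols <- ((nodes - 1) %/% nr) + 1
  s <- idmap[start[1], start[2]]; e <- idmap[end[1], end[2]]
  if (is.na(s) || is.na(e)) return(Inf)
  dist <- rep(Inf, n); dist[s] <- 0
  visited <- rep(FALSE, n)
  offs <- rbind(c(-1, -1, sqrt(2)), c(-1, 0, 1), c(-1, 1, sqrt(2)),
                c(0, -1, 1), c(0, 1, 1),
                c(1, -1, sqrt(2)), c(1, 0, 1), c(1, 1, sqrt(2)))
  repeat {
    cand <- ifelse(visited, Inf, dist)
    u <- which.min(cand)
    if (!is.finite(cand[u])) break
    visited[u] <- TRUE
    if (u == e) break
    for (k in 1:8) {
      r2 <- rows[u] + offs[k, 1]; c2 <- cols[u] + offs[k, 2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      v <- idmap[r2, c2]
      if (is.na(v) || visited[v]) next
      w <- offs[k, 3] * (step_cost[rows[u], cols[u]] + step_cost[r2, c2]) / 2
      if (dist[u] + w < dist[v]) dist[v] <- dist[u] + w
    }
  }
  dist[e]
}

# Exhaustive DFS enumeration of all simple 8-connected paths on a tiny
# admissible set; returns the minimum total cost. Only usable on corridors
# of a dozen-odd cells.
enumerate_paths_cost <- function(adm, step_cost, start, end) {
  nr <- nrow(adm); nc <- ncol(adm)
  best <- Inf
  visit <- function(r, cc, cost, seen) {
    if (cost >= best) return(invisible())
    if (r == end[1] && cc == end[2]) { best <<- cost; return(invisible()) }
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- cc + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!adm[r2, c2] || seen[r2, c2]) next
      w <- (if (dr != 0 && dc != 0) sqrt(2) else 1) *
        (step_cost[r, cc] + step_cost[r2, c2]) / 2
      seen[r2, c2] <- TRUE
      visit(r2, c2, cost + w, seen)
      seen[r2, c2] <- FALSE
    }
  }
  seen <- matrix(FALSE, nr, nc); seen[start[1], start[2]] <- TRUE
  visit(start[1], start[2], 0, seen)
  best
}

# Brute-force Euclidean distance transform: per foreground pixel, the
# minimum distance to any background pixel or to the image border.
brute_distance_transform <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(0, nr, nc)
  for (i in which(mask)) {
    r <- ((i - 1) %% nr) + 1; cc <- ((i - 1) %/% nr) + 1
    dborder <- min(r, cc, nr + 1 - r, nc + 1 - cc)
    dbg <- if (nrow(bg) > 0) sqrt(min((bg[, 1] - r)^2 + (bg[, 2] - cc)^2)) else Inf
    out[r, cc] <- min(dborder, dbg)
  }
  out
}

# Random connected-ish blobby masks for oracle-equivalence sweeps.
random_mask <- function(nr, nc, n_seeds = 3, growth = 60) {
  m <- matrix(FALSE, nr, nc)
  pts <- cbind(sample.int(nr, n_seeds, replace = TRUE),
               sample.int(nc, n_seeds, replace = TRUE))
  for (k in seq_len(n_seeds)) m[pts[k, 1], pts[k, 2]] <- TRUE
  for (it in seq_len(growth)) {
    fg <- which(m, arr.ind = TRUE)
    p <- fg[sample.int(nrow(fg), 1), ]
    q <- p + sample(c(-1, 0, 1), 2, replace = TRUE)
    if (all(q >= 1) && q[1] <= nr && q[2] <= nc) m[q[1], q[2]] <- TRUE
  }
  m
}
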