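# Independent oracles used by the tests. Deliberately naive implementations
# that share no code with the package internals.

# O(n^2) all-pairs nearest-neighbour distances.
brute_force_nnd <- function(x, y) {
  n <- length(x)
  d <- rep(Inf, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) d[i] <- min(d[i], sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2))
    }
  }
  d
}

# Stratified Monte-Carlo nearest-site integration of Voronoi areas inside a
# rectangular region: one uniform point per grid cell (jittered grid), each
# assigned to its nearest site.
mc_voronoi_areas <- function(x, y, width = 1, height = 1, grid = 1000L) {
  n_sites <- length(x)
  counts <- numeric(n_sites)
  cell_w <- width / grid; cell_h <- height / grid
  rows_per_chunk <- max(1L, floor(2e6 / grid))
  r0 <- 0L
  while (r0 < grid) {
    nr <- min(rows_per_chunk, grid - r0)
    gx <- rep((seq_len(grid) - 1) * cell_w, times = nr) +
      stats::runif(grid * nr, 0, cell_w)
    gy <- rep((r0 + seq_len(nr) - 1) * cell_h, each = grid) +
      stats::runif(grid * nr, 0, cell_h)
    best_d <- rep(Inf, length(gx)); best_i <- integer(length(gx))
    for (i in seq_len(n_sites)) {
      d2 <- (gx - x[i])^2 + (gy - y[i])^2
      upd <- d2 < best_d
      best_d[upd] <- d2[upd]; best_i[upd] <- i
    }
    counts <- counts + tabulate(best_i, nbins = n_sites)
    r0 <- r0 + nr
  }
  counts / (grid * grid) * (width * height)
}

# O(n^3) convex hull area: an edge (i, j) is on the hull iff every other
# point lies on one side; hull vertices are then ordered by angle.
brute_force_hull_area <- function(x, y) {
  n <- length(x)
  on_hull <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cr <- (x[j] - x[i]) * (y - y[i]) - (y[j] - y[i]) * (x - x[i])
      if (all(cr >= -1e-12) || all(cr <= 1e-12)) {
        on_hull[i] <- TRUE; on_hull[j] <- TRUE
      }
    }
  }
  hx <- x[on_hull]; hy <- y[on_hull]
  cx <- mean(hx); cy <- mean(hy)
  o <- order(atan2(hy - cy, hx - cx))
  hx <- hx[o]; hy <- hy[o]
  k <- length(hx)
  abs(sum(hx[c(k, seq_len(k - 1))] * hy - hx * hy[c(k, seq_len(k - 1))])) / 2
}

# Dense-arc-sampling Sholl oracle: sample each neuritic edge at n_samples
# points and count strict side changes of the distance to the soma centroid
# against each circle radius.
dense_sholl_crossings <- function(tree, step = 10, n_samples = 1e4) {
  nodes <- tree$nodes
  soma <- nodes$compartment == "soma"
  cx <- mean(nodes$x[soma]); cy <- mean(nodes$y[soma])
  dend <- which(nodes$compartment == "dendrite")
  dist_node <- sqrt((nodes$x - cx)^2 + (nodes$y - cy)^2)
  rmax <- max(dist_node[dend])
  radii <- step * seq_len(max(1, ceiling(rmax / step)))
  crossings <- integer(length(radii))
  pidx <- match(nodes$parent, nodes$id)
  tt <- seq(0, 1, length.out = n_samples)
  for (i in dend) {
    p <- pidx[i]
    if (is.na(p)) next
    sx <- nodes$x[p] + tt * (nodes$x[i] - nodes$x[p])
    sy <- nodes$y[p] + tt * (nodes$y[i] - nodes$y[p])
    d <- sqrt((sx - cx)^2 + (sy - cy)^2)
    for (k in seq_along(radii)) {
      s <- d > radii[k]
      crossings[k] <- crossings[k] + sum(s[-1] != s[-length(s)])
    }
  }
  list(radii = radii, crossings = crossings)
}

# Small fixture: a hand-built strictly bifurcating tree.
# soma(1) -> 2 -> 3 branch -> {4 tip, 5 -> branch {6 tip, 7 tip}}
fixture_tree <- function() {
  nodes <- data.frame(
    id = 1:7,
    parent = c(NA, 1, 2, 3, 3, 5, 5),
    x = c(0, 10, 20, 30, 25, 30, 20),
    y = c(0, 0, 5, 15, 20, 30, 28),
    z = c(0, 15, 15, 15, 15, 15, 15),
    radius = c(10, rep(0.5, 6)),
    compartment = c("soma", rep("dendrite", 6)),
    stratum = c(NA, rep("S1", 6)),
    stringsAsFactors = FALSE)
  neurite_tree(nodes, soma_area = 314.16, cell_id = "fix_1", subtype = "M1")
}
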