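test_that("soma equivalent diameter inverts the circle-area formula", {
  expect_equal(soma_equivalent_diameter(pi), 2)
  expect_equal(soma_equivalent_diameter(100 * pi), 20)
  # the published M2 mean diameter scale: 340.2 um^2 -> ~20.8 um
  expect_equal(soma_equivalent_diameter(340.2), 2 * sqrt(340.2 / pi))
  expect_lt(abs(soma_equivalent_diameter(340.2) - 20.82), 0.02)
  expect_error(soma_equivalent_diameter(0), class = "retmosaic_validation")
  expect_error(soma_equivalent_diameter(-5), class = "retmosaic_validation")
})

test_that("dendritic field area: square fixture and brute-force hull oracle", {
  # dendrite endpoints at the corners of a 100 um square -> 0.01 mm^2
  nodes <- data.frame(
    id = 1:5, parent = c(NA, 1, 1, 1, 1),
    x = c(0, 0, 100, 100, 0), y = c(0, 0, 0, 100, 100),
    z = 0, radius = c(10, rep(0.5, 4)),
    compartment = c("soma", rep("dendrite", 4)),
    stratum = c(NA, rep("S1", 4)), stringsAsFactors = FALSE)
  # shift first dendrite off the soma position to avoid duplicate coordinate
  nodes$x[2] <- 0.0; nodes$y[2] <- 0.0
  tr <- neurite_tree(nodes, soma_area = 300)
  expect_equal(dendritic_field_area(tr), 0.01)
  # random trees vs O(n^3) hull oracle
  for (s in 1:20) {
    tg <- generate_tree(tree_spec(n_primary = 2 + s %% 3,
                                  target_branch_points = 5 + s, seed = s))
    di <- tg$nodes$compartment == "dendrite"
    expect_equal(dendritic_field_area(tg),
                 brute_force_hull_area(tg$nodes$x[di], tg$nodes$y[di]) / 1e6,
                 tolerance = 1e-9)
  }
  # degenerate: collinear dendrites
  lin <- data.frame(id = 1:4, parent = c(NA, 1, 2, 3),
                    x = c(0, 10, 20, 30), y = 0, z = 0,
                    radius = c(10, rep(0.5, 3)),
                    compartment = c("soma", rep("dendrite", 3)),
                    stratum = c(NA, rep("S1", 3)), stringsAsFactors = FALSE)
  expect_error(dendritic_field_area(neurite_tree(lin, soma_area = 300)),
               class = "retmosaic_degenerate_field")
})

test_that("branch points and tips match hand counts and an independent traversal", {
  tr <- fixture_tree()
  expect_equal(count_branch_points(tr), 2)
  expect_equal(count_terminal_tips(tr), 3)
  # independent recursive oracle on generated trees
  recursive_counts <- function(tree) {
    nd <- tree$nodes
    kids <- function(id) nd$id[!is.na(nd$parent) & nd$parent == id &
                                 nd$compartment == "dendrite"]
    walk <- function(id) {
      ch <- kids(id)
      below <- if (length(ch)) Reduce(function(a, b) a + b, lapply(ch, walk))
               else c(bp = 0, tips = 0)
      if (nd$compartment[nd$id == id] != "dendrite") return(below)
      if (length(ch) >= 2) below + c(bp = 1, tips = 0)
      else if (length(ch) == 0) below + c(bp = 0, tips = 1)
      else below
    }
    walk(nd$id[is.na(nd$parent)])
  }
  for (s in 1:12) {
    tg <- generate_tree(tree_spec(n_primary = 1 + s %% 3,
                                  target_branch_points = s, seed = 100 + s))
    oracle <- recursive_counts(tg)
    expect_equal(count_branch_points(tg), unname(oracle["bp"]))
    expect_equal(count_terminal_tips(tg), unname(oracle["tips"]))
  }
})

test_that("Sholl profile: straight-neurite geometry and tangency convention", {
  # one straight radial neurite of length 95, step 10: 1 crossing at radii
  # 10..90, 0 at the final circle (100)
  nodes <- data.frame(id = 1:3, parent = c(NA, 1, 2),
                      x = c(0, 43, 95), y = 0, z = 0,
                      radius = c(10, 0.5, 0.5),
                      compartment = c("soma", "dendrite", "dendrite"),
                      stratum = c(NA, "S1", "S1"), stringsAsFactors = FALSE)
  tr <- neurite_tree(nodes, soma_area = 300)
  pr <- sholl_profile(tr, step = 10)
  expect_equal(pr$radii, seq(10, 100, by = 10))
  expect_equal(pr$crossings, c(rep(1L, 9), 0L))
  # an edge with both endpoints exactly at radius r (tangent chord): 0 crossings
  tang <- data.frame(id = 1:3, parent = c(NA, 1, 2),
                     x = c(0, 30, 0), y = c(0, 0, 30), z = 0,
                     radius = c(10, 0.5, 0.5),
                     compartment = c("soma", "dendrite", "dendrite"),
                     stratum = c(NA, "S1", "S1"), stringsAsFactors = FALSE)
  # soma->(30,0) ends exactly on the circle (no strict straddle) and
  # (30,0)->(0,30) is a tangent chord: both count zero at r = 30
  pt <- sholl_profile(neurite_tree(tang, soma_area = 300), step = 30)
  expect_equal(pt$crossings[pt$radii == 30], 0L)
  expect_equal(sum(pt$crossings), 0)
})

test_that("Sholl crossings equal the dense-arc-sampling oracle on generated trees", {
  for (s in 1:20) {
    tg <- generate_tree(tree_spec(n_primary = 1 + s %% 4,
                                  target_branch_points = 4 + s %% 10,
                                  seed = 200 + s))
    pr <- sholl_profile(tg, step = 25)
    oracle <- dense_sholl_crossings(tg, step = 25, n_samples = 1e4)
    expect_equal(pr$radii, oracle$radii)
    expect_equal(pr$crossings, oracle$crossings)
  }
})

test_that("Sholl area: closed forms and refinement stability", {
  # all-zero profile
  empty <- structure(list(radii = c(10, 20), crossings = c(0L, 0L), step = 10),
                     class = "sholl_profile")
  expect_equal(sholl_area(empty), 0)
  # constant 1 crossing over 10 radii -> interior trapezoid area 9
  const <- structure(list(radii = seq(10, 100, 10), crossings = rep(1L, 10),
                          step = 10), class = "sholl_profile")
  expect_equal(sholl_area(const), 9)
  # halving the step changes the area by < 5%
  tg <- generate_tree(tree_spec(n_primary = 3, target_branch_points = 18,
                                seed = 55))
  a10 <- sholl_area(sholl_profile(tg, step = 10))
  a5 <- sholl_area(sholl_profile(tg, step = 5))
  expect_lt(abs(a10 - a5) / a5, 0.05)
})

test_that("metric invariances: rigid motions and coordinate scaling", {
  tg <- generate_tree(tree_spec(n_primary = 3, target_branch_points = 15,
                                seed = 77))
  rot <- tg
  th <- 0.7
  xr <- tg$nodes$x * cos(th) - tg$nodes$y * sin(th)
  yr <- tg$nodes$x * sin(th) + tg$nodes$y * cos(th)
  rot$nodes$x <- xr + 50; rot$nodes$y <- yr - 20
  expect_equal(dendritic_field_area(rot), dendritic_field_area(tg))
  expect_equal(count_branch_points(rot), count_branch_points(tg))
  expect_equal(sholl_profile(rot, 10)$crossings, sholl_profile(tg, 10)$crossings)
  # scaling by c: hull area scales by c^2, mean Sholl radius by c
  sc <- tg; sc$nodes$x <- 2 * tg$nodes$x; sc$nodes$y <- 2 * tg$nodes$y
  expect_equal(dendritic_field_area(sc), 4 * dendritic_field_area(tg))
  p1 <- sholl_profile(tg, 10); p2 <- sholl_profile(sc, 20)
  expect_equal(p2$crossings, p1$crossings)
})

test_that("morphometry batch keeps one row per cell with failures flagged", {
  trees <- lapply(1:4, function(s)
    generate_tree(sample_tree_spec("M2", seed = s),
                  cell_id = sprintf("c%02d", s), subtype = "M2"))
  # a cell with an unbranched single dendrite node: degenerate field
  stub_nodes <- data.frame(id = 1:2, parent = c(NA, 1), x = c(0, 10),
                           y = 0, z = 0, radius = c(10, 0.5),
                           compartment = c("soma", "dendrite"),
                           stratum = c(NA, "S5"), stringsAsFactors = FALSE)
  trees[[5]] <- neurite_tree(stub_nodes, soma_area = 250, cell_id = "c05",
                             subtype = "M2")
  out <- morphometry_batch(trees)
  expect_equal(nrow(out), 5)
  expect_equal(out$cell_id, sort(out$cell_id))
  expect_equal(out$flag[out$cell_id == "c05"], "degenerate_field")
  expect_true(is.na(out$dendritic_area[out$cell_id == "c05"]))
  expect_equal(out$terminal_tips[out$cell_id == "c05"], 1)
  # duplicate ids rejected
  trees_dup <- trees[c(1, 1)]
  expect_error(morphometry_batch(trees_dup), class = "retmosaic_validation")
})
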