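ray_tree <- function(len = 20) {
  # single straight process of the given length along +x
  pts <- cbind(seq(0, len, by = 1), 0, 0)
  structure(list(
    soma_center = c(0, 0, 0), soma_radius = 2,
    nodes = data.frame(id = 1:2, x = c(0, len), y = 0, z = 0,
                       parent = c(0L, 1L), order = 0:1),
    segments = list(list(parent_node = 1L, child_node = 2L, pts = pts,
                         radii = rep(0.5, nrow(pts)), order = 1L,
                         fragmented = FALSE)),
    tip_count = 1L, junction_count = 0L, segment_count = 1L,
    n_fragmented = 0L, spec_regime = "young_like", seed = 0L),
    class = "cell_tree")
}

test_that("a 20 um ray crosses spheres at r = 1..19 only", {
  prof <- analytic_sholl(ray_tree(20), step = 1)
  expect_equal(prof$intersections[prof$radius <= 19], rep(1L, 19))
  expect_equal(prof$intersections[prof$radius >= 20], rep(0L, sum(prof$radius >= 20)))
  # the same through the graph-based profile
  g <- as_skeleton_graph(ray_tree(20))
  sp <- sholl_profile(g, c(0, 0, 0), step = 1)
  expect_equal(sp$profile$intersections, prof$intersections)
})

test_that("Y-tree counts 1 before and 2 after the branch point", {
  trunk <- cbind(seq(0, 10, 1), 0, 0)
  b1 <- cbind(seq(10, 20, 1), 0, 0)
  b2 <- cbind(10 + 0:10 * (10 / sqrt(2)) / 10, 0:10 * (10 / sqrt(2)) / 10, 0)
  tree <- ray_tree(10)
  tree$nodes <- data.frame(id = 1:4, x = c(0, 10, 20, 10 + 10 / sqrt(2)),
                           y = c(0, 0, 0, 10 / sqrt(2)), z = 0,
                           parent = c(0L, 1L, 2L, 2L), order = c(0:1, 2L, 2L))
  tree$segments <- list(
    list(parent_node = 1L, child_node = 2L, pts = trunk, radii = rep(.5, 11),
         order = 1L, fragmented = FALSE),
    list(parent_node = 2L, child_node = 3L, pts = b1, radii = rep(.5, 11),
         order = 2L, fragmented = FALSE),
    list(parent_node = 2L, child_node = 4L, pts = b2, radii = rep(.5, 11),
         order = 2L, fragmented = FALSE))
  tree$tip_count <- 2L; tree$junction_count <- 1L; tree$segment_count <- 3L
  prof <- analytic_sholl(tree, step = 1)
  expect_equal(prof$intersections[prof$radius %in% 1:9], rep(1L, 9))
  # second branch reaches radial extent 10 + 10/sqrt(2) ~ 18.5
  expect_equal(prof$intersections[prof$radius %in% 11:18], rep(2L, 8))
  expect_equal(prof$intersections[prof$radius == 19], 1L)
})

test_that("analytic Sholl equals the dense-sampling oracle on random trees", {
  spec <- phantom_spec("young_like")
  for (i in 1:12) {
    tree <- generate_cell_tree(spec, seed = 4000 + i)
    a <- analytic_sholl(tree, step = 1)
    d <- dense_sholl(tree, step = 1, r_max = max(a$radius))
    expect_identical(a$intersections, d$intersections[seq_len(nrow(a))])
  }
})

test_that("graph Sholl profile equals the analytic oracle on ground truth", {
  for (regime in c("young_like", "aged_like")) {
    spec <- phantom_spec(regime)
    for (i in 1:10) {
      tree <- generate_cell_tree(spec, seed = 5000 + i)
      a <- analytic_sholl(tree, step = 1)
      g <- as_skeleton_graph(tree)
      p <- sholl_profile(g, tree$soma_center, step = 1)
      expect_identical(p$profile$intersections, a$intersections)
    }
  }
})

test_that("intersections near the soma equal the number of primary processes", {
  # unbranched cells with a small fixed soma: every primary has crossed the
  # first shell beyond the soma and none has branched or terminated yet
  spec <- phantom_spec("young_like", tip_target = 2, n_primary = 2,
                       segment_length_mean = 12, segment_length_sd = 0.01,
                       soma_radius_range = c(2, 2))
  for (i in 1:8) {
    tree <- generate_cell_tree(spec, seed = 6000 + i)
    prof <- analytic_sholl(tree, step = 1)
    expect_equal(prof$intersections[prof$radius == 3],
                 sum(tree$nodes$parent == 1L))
  }
})

test_that("Sholl AUC follows the trapezoid convention", {
  prof <- structure(list(profile = data.frame(
    radius = 1:15, intersections = c(rep(2L, 11), rep(0L, 4))),
    soma_center = c(0, 0, 0), step = 1), class = "sholl_profile")
  s <- sholl_auc(prof)
  expect_equal(s$auc, 22)
  expect_equal(s$max_branches, 2L)
  expect_equal(s$critical_radius, 1)
  # zero profile
  z <- structure(list(profile = data.frame(radius = 1:5, intersections = 0L),
                      step = 1), class = "sholl_profile")
  expect_equal(sholl_auc(z)$auc, 0)
  expect_equal(sholl_auc(z)$max_branches, 0L)
  # linearity: tripling the counts triples the integral
  prof3 <- prof
  prof3$profile$intersections <- prof$profile$intersections * 3L
  expect_equal(sholl_auc(prof3)$auc, 3 * s$auc)
})

test_that("empty graphs give a warned all-zero profile", {
  nodes <- data.frame(id = 1L, x = 0, y = 0, z = 0, class = "isolated",
                      radius = 0.5)
  edges <- data.frame(from = integer(0), to = integer(0), length = numeric(0))
  edges$polyline <- list()
  g <- skeleton_graph(nodes, edges)
  expect_warning(p <- sholl_profile(g, c(0, 0, 0)), "empty")
  expect_true(all(p$profile$intersections == 0))
})

test_that("pooling is complete and order-invariant", {
  cells <- data.frame(cell_id = sprintf("c%02d", 1:10),
                      sample_id = rep(c("s1", "s2"), each = 5),
                      condition = rep(c("a", "b"), each = 5),
                      sholl_auc = runif(10))
  pooled <- pool_cells(cells)
  expect_equal(nrow(pooled), 10L)
  shuffled <- cells[sample(10), ]
  expect_equal(pool_cells(shuffled), pooled, ignore_attr = TRUE)
  empty <- cells
  empty$condition <- factor(empty$condition, levels = c("a", "b", "c"))
  expect_error(pool_cells(empty), "zero cells")
})
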