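test_that("degenerate branching yields a single unbranched segment", {
  spec <- phantom_spec("young_like", tip_target = 1, n_primary = 1)
  expect_true(all(spec$branch_probs == 0))
  tree <- generate_cell_tree(spec, seed = 5)
  expect_equal(tree$tip_count, 1L)
  expect_equal(tree$junction_count, 0L)
  expect_equal(tree$segment_count, 1L)
})

test_that("tree generation is a pure function of (spec, seed)", {
  spec <- phantom_spec("young_like")
  expect_identical(generate_cell_tree(spec, seed = 42),
                   generate_cell_tree(spec, seed = 42))
  expect_false(identical(generate_cell_tree(spec, seed = 42),
                         generate_cell_tree(spec, seed = 43)))
})

test_that("generated graphs are rooted trees; fragmentation adds components", {
  spec <- phantom_spec("aged_like")
  for (i in 1:20) {
    tree <- generate_cell_tree(spec, seed = 300 + i)
    nd <- tree$nodes
    # acyclic + connected: every non-root node has exactly one parent and
    # all parents exist
    expect_equal(nrow(nd), tree$segment_count + 1L)
    expect_true(all(nd$parent[-1] %in% nd$id))
    expect_true(all(table(nd$id) == 1))
    expect_true(all(vapply(tree$segments, function(s)
      all(is.finite(s$pts)) && all(s$radii > 0), logical(1))))
    expect_equal(tree$tip_count + tree$junction_count, tree$segment_count)
    # removing fragmented edges splits the tree into 1 + n_frag components
    keep <- !vapply(tree$segments, function(s) isTRUE(s$fragmented), logical(1))
    g <- igraph::graph_from_edgelist(cbind(
      match(vapply(tree$segments[keep], function(s) s$parent_node, integer(1)), nd$id),
      match(vapply(tree$segments[keep], function(s) s$child_node, integer(1)), nd$id)),
      directed = FALSE)
    g <- igraph::add_vertices(g, max(0, nrow(nd) - igraph::vcount(g)))
    expect_equal(igraph::components(g)$no, 1L + tree$n_fragmented)
  }
})

test_that("regime calibration hits the target tip counts within 20%", {
  for (regime in c("young_like", "aged_like")) {
    spec <- phantom_spec(regime)
    tips <- vapply(1:150, function(i) generate_cell_tree(spec, seed = i)$tip_count,
                   integer(1))
    expect_gt(mean(tips), 0.8 * spec$tip_target)
    expect_lt(mean(tips), 1.2 * spec$tip_target)
  }
  # expected-tip recursion matches a direct Monte-Carlo of the pure model
  expect_equal(expected_tip_count(c(0.5, 0), 2), 2 * (0.5 + 0.5 * 2))
})

test_that("noiseless rasterization is invertible by thresholding", {
  cc <- cached_cell()
  rec <- cc$ras$stack$voxels > cc$spec$background_level + 1e-9
  expect_identical(as.logical(rec), as.logical(cc$ras$mask))
})

test_that("multi-cell field bookkeeping: 3 cells give labels {1,2,3}", {
  spec <- noiseless_spec(cells_per_field = 3, field_shape = c(25L, 300L, 300L))
  fld <- rasterize_field(spec, seed = 11)
  expect_equal(nrow(fld$ground_truth$soma_centers), 3L)
  expect_setequal(setdiff(unique(as.integer(fld$ground_truth$labels)), 0L), 1:3)
  expect_equal(nrow(fld$ground_truth$table), 3L)
})

test_that("cohort manifest is complete, reproducible, and regime-ordered", {
  conds <- list(young_naive = phantom_spec("young_like"),
                aged_naive = phantom_spec("aged_like"))
  out1 <- generate_cohort(conds, n_cells = 4, master_seed = 7, write_stacks = FALSE)
  out2 <- generate_cohort(conds, n_cells = 4, master_seed = 7, write_stacks = FALSE)
  expect_equal(nrow(out1$manifest), 8L)
  expect_identical(out1$manifest, out2$manifest)
  m <- out1$manifest
  expect_gt(mean(m$true_tip_count[m$condition == "young_naive"]),
            mean(m$true_tip_count[m$condition == "aged_naive"]))
})

test_that("cohort on disk round-trips through TIFF with identical checksums", {
  td <- withr::local_tempdir()
  conds <- list(a = noiseless_spec())
  m1 <- generate_cohort(conds, n_cells = 3, out_dir = file.path(td, "r1"),
                        master_seed = 3)
  m2 <- generate_cohort(conds, n_cells = 3, out_dir = file.path(td, "r2"),
                        master_seed = 3)
  s1 <- unname(tools::md5sum(m1$stack))
  s2 <- unname(tools::md5sum(m2$stack))
  expect_identical(s1, s2)
  st <- suppressMessages(read_stack(m1$stack[1]))
  expect_equal(st$spacing, conds$a$voxel_spacing)
  expect_equal(length(dim(st$voxels)), 3L)
})
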