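test_that("thinning fixes already-thin lines and preserves topology", {
  m <- array(FALSE, c(3, 3, 20)); m[2, 2, ] <- TRUE
  sk <- skeletonize_cell(m, c(1, 1, 1))
  expect_identical(as.logical(sk$mask), as.logical(m))
  # solid cylinder thins to one curve near the axis with exactly 2 endpoints
  cyl <- array(FALSE, c(9, 9, 30))
  for (z in 1:9) for (y in 1:9) if ((z - 5)^2 + (y - 5)^2 <= 9) cyl[z, y, ] <- TRUE
  sk2 <- classify_voxels(skeletonize_cell(cyl, c(1, 1, 1)))
  expect_equal(sum(sk2$class == 1L), 2L)
  expect_equal(sum(sk2$class == 3L), 0L)
  lin <- which(sk2$mask)
  iz <- ((lin - 1) %% 9) + 1; iy <- (((lin - 1) %/% 9) %% 9) + 1
  expect_true(all(abs(iz - 5) <= 1 & abs(iy - 5) <= 1))
  # two disjoint blobs give two skeleton components
  two <- array(FALSE, c(10, 10, 10))
  two[2:4, 2:4, 2:4] <- TRUE; two[7:9, 7:9, 7:9] <- TRUE
  sk3 <- skeletonize_cell(two, c(1, 1, 1))
  lab <- migmorph:::cpp_label3d(as.logical(sk3$mask), dim(two), 26L)
  expect_equal(max(lab), 2L)
  expect_error(skeletonize_cell(array(FALSE, c(3, 3, 3)), c(1, 1, 1)), "empty")
})

test_that("voxel classes follow the 26-neighbourhood degree rule", {
  m <- array(FALSE, c(3, 3, 5)); m[2, 2, 2:4] <- TRUE
  cls <- classify_voxels(structure(list(mask = m, class = NULL,
                                        spacing = c(1, 1, 1)),
                                   class = "skeleton_voxels"))$class
  expect_equal(cls[2, 2, 2], 1L)  # endpoint
  expect_equal(cls[2, 2, 3], 2L)  # slab
  expect_equal(cls[2, 2, 4], 1L)
  # plus sign (arm length 2): centre junction, four endpoint tips
  p <- array(FALSE, c(3, 5, 5))
  p[2, 3, 1:5] <- TRUE; p[2, 1:5, 3] <- TRUE
  clsp <- classify_voxels(structure(list(mask = p, class = NULL,
                                         spacing = c(1, 1, 1)),
                                    class = "skeleton_voxels"))$class
  expect_equal(clsp[2, 3, 3], 3L)
  expect_equal(sum(clsp == 1L), 4L)
  # isolated voxel
  iso <- array(FALSE, c(3, 3, 3)); iso[2, 2, 2] <- TRUE
  clsi <- classify_voxels(structure(list(mask = iso, class = NULL,
                                         spacing = c(1, 1, 1)),
                                    class = "skeleton_voxels"))$class
  expect_equal(clsi[2, 2, 2], 4L)
  # handshake: sum of degrees equals twice the adjacency count
  cc <- cached_cell()
  sk <- classify_voxels(skeletonize_cell(cc$ras$mask, cc$spec$voxel_spacing))
  deg <- migmorph:::cpp_neighbor_count26(as.logical(sk$mask), dim(sk$mask))
  degs <- deg[!is.na(deg)]
  expect_equal(sum(degs) %% 2, 0)
  lin <- which(sk$mask)
  dims <- dim(sk$mask)
  adj <- 0L
  izyx <- cbind(((lin - 1) %% dims[1]) + 1, (((lin - 1) %/% dims[1]) %% dims[2]) + 1,
                ((lin - 1) %/% (dims[1] * dims[2])) + 1)
  keyset <- new.env()
  for (r in seq_len(nrow(izyx))) assign(paste(izyx[r, ], collapse = ","), TRUE, keyset)
  for (r in seq_len(nrow(izyx))) for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    if (exists(paste(izyx[r, ] + c(dz, dy, dx), collapse = ","), keyset))
      adj <- adj + 1L
  }
  expect_equal(sum(degs), adj)  # each adjacency counted from both ends
})

test_that("graph construction recovers simple topologies", {
  # Y: three arms meeting at one voxel
  y <- array(FALSE, c(3, 9, 9))
  y[2, 5, 1:5] <- TRUE          # horizontal arm into the centre
  y[2, 1:4, 5] <- TRUE          # vertical arm
  y[2, 6:9, 6:9][cbind(1:4, 1:4)] <- TRUE  # diagonal arm
  sk <- classify_voxels(structure(list(mask = y, class = NULL,
                                       spacing = c(1, 1, 1)),
                                  class = "skeleton_voxels"))
  g <- build_graph(sk, prune_terminal_um = 0, merge_junction_um = 0)
  expect_equal(g$segment_count, 3L)
  expect_equal(sum(g$nodes$class == "junction"), 1L)
  expect_equal(sum(g$nodes$class == "endpoint"), 3L)
  expect_equal(g$component_count, 1L)
})

test_that("adjacent junction voxels merge into a single junction node", {
  # a line crossed by two arms anchored on neighbouring voxels: the two
  # junction voxels are 26-adjacent and must become one node, with no
  # spurious 1-voxel edge between them
  m <- array(FALSE, c(3, 7, 8))
  m[2, 4, 1:8] <- TRUE        # horizontal line
  m[2, 1:3, 4] <- TRUE        # arm up at x = 4
  m[2, 5:7, 5] <- TRUE        # arm down at x = 5
  sk <- classify_voxels(structure(list(mask = m, class = NULL,
                                       spacing = c(1, 1, 1)),
                                  class = "skeleton_voxels"))
  g <- build_graph(sk, prune_terminal_um = 0, merge_junction_um = 0)
  expect_equal(sum(g$nodes$class == "junction"), 1L)
  expect_equal(sum(g$nodes$class == "endpoint"), 4L)
  expect_equal(g$segment_count, 4L)
})

test_that("longest path equals the graph diameter", {
  # single edge
  nodes <- data.frame(id = 1:2, x = c(0, 3), y = 0, z = 0,
                      class = c("endpoint", "endpoint"), radius = 0.5)
  edges <- data.frame(from = 1L, to = 2L, length = 3)
  edges$polyline <- list(cbind(c(0, 3), 0, 0))
  g1 <- skeleton_graph(nodes, edges)
  expect_equal(longest_path(g1), 3)
  # Y with 10 um trunk and two 10 um branches: tip-to-tip 20
  ny <- data.frame(id = 1:4, x = c(0, 10, 17, 17), y = c(0, 0, 7, -7), z = 0,
                   class = c("soma", "junction", "endpoint", "endpoint"),
                   radius = 0.5)
  ey <- data.frame(from = c(1L, 2L, 2L), to = c(2L, 3L, 4L), length = c(10, 10, 10))
  ey$polyline <- list(cbind(c(0, 10), 0, 0), cbind(c(10, 17), c(0, 7), 0),
                      cbind(c(10, 17), c(0, -7), 0))
  expect_equal(longest_path(skeleton_graph(ny, ey)), 20)
  # all-pairs shortest-path oracle on random phantom trees
  for (i in 1:10) {
    tree <- generate_cell_tree(phantom_spec("young_like"), seed = 2200 + i)
    g <- as_skeleton_graph(tree)
    expect_equal(longest_path(g), fw_diameter(g), tolerance = 1e-9)
  }
})

test_that("longest path and segment count are stable under grid reorientation", {
  # on an isotropic render, axis permutation and 90-degree rotation leave
  # the derived morphometrics essentially unchanged (directional thinning
  # is equivariant up to sub-voxel differences)
  spec <- phantom_spec("young_like", voxel_spacing = c(0.5, 0.5, 0.5),
                       psf_sigma = c(0, 0, 0), snr = Inf,
                       min_radius = 0.8, initial_radius = 1.0,
                       z_half_extent = 12)
  tree <- generate_cell_tree(spec, seed = 42)
  ras <- rasterize_cell(tree, spec, seed = 1)
  m <- as.logical(ras$mask); dim(m) <- dim(ras$mask)
  iso <- c(1, 1, 1)
  gb <- build_graph(classify_voxels(skeletonize_cell(m, iso)))
  perm <- aperm(m, c(3, 1, 2))
  gp <- build_graph(classify_voxels(skeletonize_cell(perm, iso)))
  expect_lt(abs(gp$longest_path_um - gb$longest_path_um) / gb$longest_path_um, 0.03)
  expect_lte(abs(gp$segment_count - gb$segment_count), 1)
  # 90 degree rotation in the (y, x) plane
  rot <- aperm(m, c(1, 3, 2))[, , rev(seq_len(dim(m)[2])), drop = FALSE]
  dim(rot) <- dim(m)[c(1, 3, 2)]
  gr <- build_graph(classify_voxels(skeletonize_cell(rot, iso)))
  expect_lte(abs(gr$segment_count - gb$segment_count), 1)
  expect_lt(abs(gr$longest_path_um - gb$longest_path_um) / gb$longest_path_um, 0.03)
})
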