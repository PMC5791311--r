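test_that("Li threshold separates a two-point histogram exactly", {
  x <- c(rep(0, 1000), rep(100, 1000))
  t <- li_threshold(x)
  expect_gt(t, 0); expect_lt(t, 100)
  expect_equal(sum(x > t), 1000)
  expect_error(li_threshold(rep(5, 100)), "constant")
})

test_that("Li threshold matches the exhaustive cross-entropy minimizer", {
  set.seed(19)
  for (i in 1:6) {
    x <- c(rnorm(5e4, 30, 10), rnorm(5e4, 120, 10))
    x <- pmax(x, 0)
    expect_lt(abs(li_threshold(x) - li_scan_oracle(x)), 1.5)
  }
})

test_that("Li threshold is shift-equivariant", {
  set.seed(7)
  x <- c(rnorm(2e4, 40, 8), rnorm(2e4, 130, 12))
  x <- pmax(x, 0)
  t0 <- li_threshold(x)
  for (cshift in c(15, 250)) {
    expect_equal(li_threshold(x + cshift), t0 + cshift, tolerance = 1e-9)
  }
})

test_that("contrast enhancement preserves constants and class separability", {
  vox <- array(500, c(3, 140, 140))
  st <- image_stack(vox, c(1, 0.3, 0.3))
  enh <- enhance_local_contrast(st, 60, 3)
  expect_equal(enh$voxels, vox)
  # two-level image: order preserved, levels distinct
  vox2 <- vox
  vox2[, 40:70, 40:70] <- 20000
  enh2 <- enhance_local_contrast(image_stack(vox2, c(1, 0.3, 0.3)), 60, 3)
  lo <- enh2$voxels[2, 10, 10]; hi <- enh2$voxels[2, 55, 55]
  expect_gt(hi, lo)
  # Otsu inter-class separability is not degraded on a dim-process phantom
  cc <- cached_cell()
  dim_stack <- image_stack(cc$ras$stack$voxels * 0.05, cc$ras$stack$spacing)
  enh3 <- enhance_local_contrast(dim_stack, 60, 3)
  otsu_var <- function(v, mask) {
    w <- mean(mask)
    w * (1 - w) * (mean(v[mask]) - mean(v[!mask]))^2 / stats::var(as.numeric(v))
  }
  m <- as.logical(cc$ras$mask)
  expect_gte(otsu_var(enh3$voxels, m) + 1e-9, otsu_var(dim_stack$voxels, m))
})

test_that("mask simplification follows discrete ball morphology", {
  # single voxel: removed by opening radius 1
  m <- array(FALSE, c(7, 7, 7)); m[4, 4, 4] <- TRUE
  expect_false(any(simplify_mask(m, 1, 0)))
  # solid cube: unchanged (rims shaved by the opening are restored by the
  # conditional dilation), and re-application is a fixed point
  cube <- array(FALSE, c(14, 14, 14)); cube[3:12, 3:12, 3:12] <- TRUE
  s1 <- simplify_mask(cube, 1, 1)
  expect_equal(sum(s1), sum(cube))
  expect_identical(simplify_mask(s1, 1, 1), s1)
  # two cubes with a 1-voxel gap: bridged by closing radius 1
  two <- array(FALSE, c(13, 13, 13))
  two[4:9, 4:9, 2:6] <- TRUE; two[4:9, 4:9, 8:12] <- TRUE
  closed <- simplify_mask(two, 0, 1)
  lab <- migmorph:::cpp_label3d(as.logical(closed), dim(closed), 26L)
  expect_equal(max(lab), 1L)
})

test_that("Phansalkar threshold matches its closed form on a constant slice", {
  sl <- matrix(0.5, 45, 45)
  th <- phansalkar_threshold(sl, radius_px = 20)
  expect_equal(as.numeric(th), rep(0.5 * (1 + 2 * exp(-5) - 0.25), length(th)),
               tolerance = 1e-6)
  expect_true(all(sl > th))   # the whole slice lies above its local threshold
  # all-zero slice: threshold 0, nothing strictly above
  z <- matrix(0, 45, 45)
  expect_true(all(phansalkar_threshold(z, 20) == 0))
  st <- image_stack(array(0, c(2, 45, 45)), c(1, 1, 1))
  expect_equal(nrow(phansalkar_soma_detect(st, 20)$somata), 0L)
  expect_error(phansalkar_threshold(matrix(0, 10, 10), 20), "radius")
})

test_that("soma detection finds one soma per noiseless cell", {
  cc <- cached_cell()
  somata <- phansalkar_soma_detect(cc$ras$stack)
  expect_equal(nrow(somata$somata), 1L)
  d <- sqrt(sum((c(somata$somata$x, somata$somata$y, somata$somata$z) -
                 cc$ras$tree$soma_center)^2))
  expect_lt(d, 2)
  expect_gt(somata$somata$volume, 50)
  expect_lt(somata$somata$volume, 1500)
})

test_that("watershed respects markers, conserves the mask, splits on the midplane", {
  dims <- c(20L, 40L, 60L)
  sp <- c(1, 0.5, 0.5)
  grid <- expand.grid(iz = 1:dims[1], iy = 1:dims[2], ix = 1:dims[3])
  px <- (grid$ix - 0.5) * sp[3]; py <- (grid$iy - 0.5) * sp[2]; pz <- (grid$iz - 0.5) * sp[1]
  c1 <- c(9, 10, 10); c2 <- c(21, 10, 10)
  d1 <- sqrt((px - c1[1])^2 + (py - c1[2])^2 + (pz - c1[3])^2)
  d2 <- sqrt((px - c2[1])^2 + (py - c2[2])^2 + (pz - c2[3])^2)
  mask <- array(d1 <= 8 | d2 <= 8, dims)
  vox1 <- which(array(d1 < 1, dims)); vox2 <- which(array(d2 < 1, dims))
  somata <- structure(list(
    somata = data.frame(id = 1:2, x = c(c1[1], c2[1]), y = c(c1[2], c2[2]),
                        z = c(c1[3], c2[3]), volume = c(4, 4),
                        mean_intensity = c(1, 1)),
    voxels = list(vox1, vox2), mask = NULL, spacing = sp), class = "soma_set")
  lm <- watershed_split(mask, somata, sp)
  lab <- lm$labels
  # conservation: union of basins = mask, basins disjoint by construction
  expect_identical(as.logical(lab > 0), as.logical(mask))
  expect_setequal(unique(as.integer(lab[lab > 0])), 1:2)
  # nearest-centre assignment away from the midplane
  off_mid <- abs(d1 - d2) > 1
  sel <- as.logical(mask) & off_mid
  expect_true(all((lab[sel] == 1) == (d1[sel] < d2[sel])))
  # one blob, one marker: basin equals mask
  mask1 <- array(d1 <= 8, dims)
  lm1 <- watershed_split(mask1, structure(list(
    somata = somata$somata[1, ], voxels = list(vox1), spacing = sp),
    class = "soma_set"), sp)
  expect_identical(as.logical(lm1$labels > 0), as.logical(mask1))
  # soma outside the mask is rejected with a warning
  far <- which(array(px > 28 & py > 18, dims))[1]
  somata_bad <- structure(list(
    somata = data.frame(id = 1, x = 0, y = 0, z = 0, volume = 1, mean_intensity = 1),
    voxels = list(far), spacing = sp), class = "soma_set")
  expect_warning(expect_warning(watershed_split(mask1, somata_bad, sp),
                                "outside"), "no usable")
})

test_that("individual-cell filter rejects border, multi-soma and off-gate cells", {
  dims <- c(10L, 30L, 30L)
  sp <- c(1, 1, 1)
  lab <- array(0L, dims)
  lab[2:5, 2:6, 2:6] <- 1L         # touches near-border? no: starts at 2
  lab[1, 10, 10] <- 2L             # on the border
  lab[7:9, 20:26, 20:26] <- 3L
  soma_vox <- list(which(lab == 1L)[1:3], which(lab == 2L)[1],
                   which(lab == 3L)[1:3], which(lab == 3L)[10:12])
  somata <- structure(list(
    somata = data.frame(id = 1:4, x = 0, y = 0, z = 0, volume = 100,
                        mean_intensity = 1),
    voxels = soma_vox, spacing = sp), class = "soma_set")
  lm <- structure(list(labels = lab, spacing = sp), class = "cell_label_map")
  out <- filter_individual_cells(lm, somata, min_volume = 50, max_volume = 1000)
  cells <- out$cells
  expect_true(cells$accepted[1])
  expect_equal(cells$reason[2], "border")
  expect_equal(cells$reason[3], "multi-soma")
  # shrink the gate so cell 1 fails on volume
  out2 <- filter_individual_cells(lm, somata, min_volume = 150, max_volume = 1000)
  expect_equal(out2$cells$reason[1], "too-small")
})

test_that("segmentation chain recovers noiseless cells with high overlap", {
  cfg <- pipeline_config()
  spec <- noiseless_spec()
  for (i in 1:3) {
    tree <- generate_cell_tree(spec, seed = 800 + i)
    ras <- rasterize_cell(tree, spec, seed = 1)
    seg <- segment_stack(ras$stack, cfg)
    cells <- seg$labels$cells
    expect_equal(sum(cells$accepted), 1L)
    got <- seg$labels$labels == cells$id[cells$accepted]
    truth <- as.logical(ras$mask)
    jac <- sum(got & truth) / sum(got | truth)
    expect_gte(jac, 0.99)
  }
})
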