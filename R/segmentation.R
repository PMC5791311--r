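# Binary ball morphology via the exact Euclidean distance transform:
# erosion keeps voxels farther than r from background, dilation keeps voxels
# within r of foreground; both exact for the discrete ball element. With
# slicewise = TRUE the ball is two-dimensional (the z axis is effectively
# disconnected), matching binary open/close tools that process stacks slice
# by slice.
ball_erode <- function(mask, r, slicewise = FALSE) {
  if (r <= 0) return(mask)
  dims <- dim(mask)
  sp <- if (slicewise) c(1e9, 1, 1) else c(1, 1, 1)
  d2 <- cpp_sqdist_to_true(!mask, dims, sp)
  out <- d2 > r^2
  dim(out) <- dims
  out
}

ball_dilate <- function(mask, r, slicewise = FALSE) {
  if (r <= 0) return(mask)
  dims <- dim(mask)
  if (!any(mask)) return(mask)
  sp <- if (slicewise) c(1e9, 1, 1) else c(1, 1, 1)
  d2 <- cpp_sqdist_to_true(as.logical(mask), dims, sp)
  out <- d2 <= r^2
  dim(out) <- dims
  out
}

#' Slice-wise local contrast enhancement (CLAHE)
#'
#' Contrast-limited adaptive histogram equalization applied per z-slice,
#' matching the behaviour of the slice-wise enhancement tools this chain
#' emulates. Intensities are treated as 16-bit (range 0-65535); the output
#' occupies the same range. Constant slices pass through unchanged.
#'
#' @param stack an [image_stack()].
#' @param block_radius_px half-size of the local histogram window; the slice
#'   is tiled into windows of about (2 radius + 1) px.
#' @param max_slope clip limit of the equalization slope.
#' @param bins histogram bins.
#' @return enhanced [image_stack()].
#' @export
enhance_local_contrast <- function(stack, block_radius_px = 63, max_slope = 3,
                                   bins = 256) {
  stopifnot(inherits(stack, "image_stack"), block_radius_px >= 1)
  d <- dim(stack$voxels)
  if (2 * block_radius_px + 1 > min(d[2], d[3]))
    stop("block radius larger than slice")
  rng <- 65535
  out <- stack$voxels
  ntx <- max(2L, round(d[3] / (2 * block_radius_px + 1)))
  nty <- max(2L, round(d[2] / (2 * block_radius_px + 1)))
  # the equalizer needs tile counts dividing the slice; pad by edge
  # replication and crop back
  py <- (nty - d[2] %% nty) %% nty
  px <- (ntx - d[3] %% ntx) %% ntx
  for (z in seq_len(d[1])) {
    sl <- stack$voxels[z, , ]
    if (diff(range(sl)) == 0) next
    v <- pmin(pmax(sl / rng, 0), 1)
    # equalization is undefined on quasi-constant slices (one histogram bin
    # holding nearly everything, e.g. an exactly uniform background): pass
    # them through unchanged
    if (max(tabulate(pmin(floor(v * bins), bins - 1) + 1L, nbins = bins)) >
        0.9 * length(v)) next
    if (py > 0) v <- rbind(v, v[rep(nrow(v), py), , drop = FALSE])
    if (px > 0) v <- cbind(v, v[, rep(ncol(v), px), drop = FALSE])
    e <- EBImage::clahe(v, nx = ntx, ny = nty, bins = bins,
                        limit = max_slope, keep.range = FALSE)
    em <- EBImage::imageData(e)
    out[z, , ] <- em[seq_len(d[2]), seq_len(d[3])] * rng
  }
  image_stack(out, stack$spacing, stack$source_path)
}

#' Li minimum-cross-entropy threshold
#'
#' Iterative scheme of Li & Tam: with below/above-threshold means mu_b and
#' mu_f of the (minimum-shifted) intensities, the update is
#' t <- (mu_f - mu_b) / (ln mu_f - ln mu_b), iterated until the change is
#' below `tol` gray levels, initialized at the image mean (the convention
#' of the reference implementations), then snapped to the neighbouring
#' discrete minimum of the cross-entropy objective. The minimum shift makes
#' the result exactly shift-equivariant. Applied once to the whole 3D stack
#' by default. For well-separated histograms with the background mode near
#' the intensity floor the result coincides with the global cross-entropy
#' minimizer; strongly overlapping or floor-distant mixtures can converge
#' to a different stationary point.
#'
#' @param stack an [image_stack()] or numeric array/vector.
#' @param tol convergence tolerance, gray levels (default 0.5).
#' @param max_iter iteration cap (default 100).
#' @return threshold on the original intensity scale.
#' @export
li_threshold <- function(stack, tol = 0.5, max_iter = 100L) {
  x <- if (inherits(stack, "image_stack")) as.numeric(stack$voxels) else as.numeric(stack)
  mn <- min(x)
  y <- x - mn
  K <- as.integer(ceiling(max(y)))
  if (K == 0L) stop("constant image has no threshold")
  # integer-gray-level histogram for O(1) class means per iteration
  bin <- pmin(as.integer(floor(y)), K)
  cnt <- tabulate(bin + 1L, nbins = K + 1L)
  vals <- 0:K
  csum_n <- cumsum(cnt)
  csum_v <- cumsum(cnt * vals)
  N <- csum_n[K + 1L]; S <- csum_v[K + 1L]
  eps <- 0.05
  class_stats <- function(t) {
    i <- max(0L, min(K - 1L, as.integer(floor(t))))
    nb <- csum_n[i + 1L]; sb <- csum_v[i + 1L]
    list(nb = nb, sb = sb, nf = N - nb, sf = S - sb)
  }
  objective <- function(t) {
    cs <- class_stats(t)
    if (cs$nb == 0L || cs$nf == 0L) return(Inf)
    -(cs$sb * log(max(cs$sb / cs$nb, eps)) + cs$sf * log(max(cs$sf / cs$nf, eps)))
  }
  iterate <- function(t0) {
    t_cur <- t0
    for (it in seq_len(max_iter)) {
      cs <- class_stats(t_cur)
      if (cs$nb == 0L) { t_cur <- t_cur + 1; next }
      if (cs$nf == 0L) { t_cur <- t_cur - 1; next }
      mu_b <- max(cs$sb / cs$nb, eps)
      mu_f <- max(cs$sf / cs$nf, mu_b + eps)
      t_new <- (mu_f - mu_b) / (log(mu_f) - log(mu_b))
      if (abs(t_new - t_cur) < tol) return(t_new)
      t_cur <- t_new
    }
    t_cur
  }
  # initialize at the image mean (the convention of the reference tools);
  # then snap to the neighbouring discrete minimum of the exact (unbinned)
  # cross-entropy, which removes the stopping and binning error
  t_star <- iterate(S / N)
  raw_objective <- function(t) {
    b <- y[y <= t]; f <- y[y > t]
    if (!length(b) || !length(f)) return(Inf)
    -(sum(b) * log(max(mean(b), eps)) + sum(f) * log(max(mean(f), eps)))
  }
  win <- max(0L, min(K - 1L, as.integer(floor(t_star)))) + (-4:4)
  win <- win[win >= 0 & win <= K - 1] + 0.5
  obj <- vapply(win, raw_objective, numeric(1))
  if (is.finite(min(obj)) && min(obj) < raw_objective(t_star))
    t_star <- win[which.min(obj)]
  t_star + mn
}

#' Morphological mask simplification
#'
#' Opening then closing with discrete disk structuring elements applied per
#' z-slice (the slice-wise behaviour of the standard binary open/close
#' stack tools; a 3D ball at 1 um axial spacing would erase every
#' single-slice-thick process). Radii are in pixels. The opening is
#' followed by one conditional dilation inside the original mask (opening
#' by partial reconstruction): noise specks smaller than the element are
#' removed as by a plain opening, but the one-pixel rims a plain opening
#' shaves off 2-3 pixel wide processes are restored. Re-application with
#' the same radii is a fixed point on simple shapes.
#'
#' @param mask logical 3D array.
#' @param opening_radius_px,closing_radius_px disk radii in pixels (>= 0).
#' @return simplified logical array.
#' @export
simplify_mask <- function(mask, opening_radius_px = 1, closing_radius_px = 1) {
  stopifnot(opening_radius_px >= 0, closing_radius_px >= 0)
  m <- mask
  if (opening_radius_px > 0) {
    m <- ball_dilate(ball_erode(mask, opening_radius_px, TRUE),
                     opening_radius_px, TRUE)
    # conditional dilation in 3D so single-slice rims are also recovered
    # from their axial neighbours
    m <- ball_dilate(m, 1, FALSE) & mask
    dim(m) <- dim(mask)
  }
  m <- ball_erode(ball_dilate(m, closing_radius_px, TRUE),
                  closing_radius_px, TRUE)
  m
}

#' Phansalkar local threshold of one slice
#'
#' t(x) = m(x) (1 + p exp(-q m(x)) + k (s(x)/R - 1)) with m, s the local
#' mean and standard deviation in a disk of `radius_px`, on intensities
#' normalized to [0, 1].
#'
#' @param slice numeric matrix, values in [0, 1].
#' @param radius_px disk radius in pixels.
#' @param k,p,q,r constants (published defaults 0.25, 2, 10, 0.5).
#' @return matrix of local thresholds.
#' @export
phansalkar_threshold <- function(slice, radius_px = 20L, k = 0.25, p = 2,
                                 q = 10, r = 0.5) {
  if (2 * radius_px + 1 > min(dim(slice))) stop("radius larger than slice")
  ms <- cpp_disk_mean_sd(slice, as.integer(radius_px))
  m <- ms$mean; s <- ms$sd
  m * (1 + p * exp(-q * m) + k * (s / r - 1))
}

#' Soma detection by slice-wise Phansalkar thresholding
#'
#' Intensities are normalized to [0, 1] (by the stack maximum when values
#' exceed 1, otherwise taken as already normalized), thresholded per slice
#' with [phansalkar_threshold()] (strictly above), assembled into 3D, opened
#' with a small ball to strip thin processes, grouped by 26-connectivity,
#' and volume-gated. Centroids are physical voxel-centre coordinates.
#'
#' @param stack an [image_stack()].
#' @param radius_px disk radius (default 20 px).
#' @param k,p,q,r Phansalkar constants.
#' @param opening_px in-plane disk opening radius applied before grouping (default 3).
#' @param min_volume,max_volume soma volume gate, um^3.
#' @return object of class `soma_set`: data.frame `somata` (id, x, y, z,
#'   volume, mean_intensity), list `voxels` of linear index sets, logical
#'   `mask`.
#' @export
phansalkar_soma_detect <- function(stack, radius_px = 20L, k = 0.25, p = 2,
                                   q = 10, r = 0.5, opening_px = 3,
                                   min_volume = 25, max_volume = 1500) {
  stopifnot(inherits(stack, "image_stack"), radius_px >= 1)
  d <- dim(stack$voxels)
  # normalize to [0, 1] by the stack maximum: the local threshold formula
  # assumes bright objects near 1
  denom <- if (max(stack$voxels) > 1) max(stack$voxels) else 1
  above <- array(FALSE, d)
  for (z in seq_len(d[1])) {
    sl <- pmin(pmax(stack$voxels[z, , ] / denom, 0), 1)
    th <- phansalkar_threshold(sl, radius_px, k, p, q, r)
    above[z, , ] <- sl > th
  }
  opened <- ball_dilate(ball_erode(above, opening_px, TRUE), opening_px, TRUE)
  lab <- cpp_label3d(opened, d, 26L)
  voxvol <- prod(stack$spacing)
  ids <- setdiff(unique(lab), 0L)
  keep <- list(); rows <- list()
  next_id <- 0L
  for (i in ids) {
    vox <- which(lab == i)
    vol <- length(vox) * voxvol
    if (vol < min_volume || vol > max_volume) next
    next_id <- next_id + 1L
    nz <- d[1]; ny <- d[2]
    iz <- ((vox - 1L) %% nz) + 1L
    iy <- (((vox - 1L) %/% nz) %% ny) + 1L
    ix <- ((vox - 1L) %/% (nz * ny)) + 1L
    ph <- vox_phys(iz, iy, ix, stack$spacing)
    rows[[next_id]] <- data.frame(id = next_id, x = mean(ph[, 1]), y = mean(ph[, 2]),
                                  z = mean(ph[, 3]), volume = vol,
                                  mean_intensity = mean(stack$voxels[vox]))
    keep[[next_id]] <- vox
  }
  somata <- if (next_id) do.call(rbind, rows)
            else data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                            z = numeric(0), volume = numeric(0),
                            mean_intensity = numeric(0))
  structure(list(somata = somata, voxels = keep, mask = opened,
                 spacing = stack$spacing), class = "soma_set")
}

#' @export
print.soma_set <- function(x, ...) {
  cat(sprintf("soma_set: %d somata, volumes %s um^3\n", nrow(x$somata),
              if (nrow(x$somata)) paste(round(range(x$somata$volume)), collapse = "-")
              else "-"))
  invisible(x)
}

#' Marker-controlled 3D watershed split of a cell mask
#'
#' Floods the negated Euclidean distance transform of the mask (physical-um
#' distances) from the soma voxel sets; every reachable foreground voxel is
#' assigned to exactly one soma's basin, background stays 0. Seeds are
#' queued in increasing soma-id order and equal-relief ties resolve by
#' insertion order, so the split is deterministic. Somata lying outside the
#' mask are dropped with a warning; with no usable soma, an empty label map
#' is returned with a warning.
#'
#' @param mask logical 3D array.
#' @param somata a `soma_set` from [phansalkar_soma_detect()].
#' @param spacing (dz, dy, dx) um.
#' @param adopt_fragments_um detached foreground components (no path to any
#'   marker) are assigned to the nearest basin within this distance (um);
#'   keeps dystrophic fragments and spheroids with their parent cell. 0
#'   disables adoption. Default 6.
#' @return object of class `cell_label_map`: integer `labels` array,
#'   `spacing`, and the seeding `somata` table.
#' @export
watershed_split <- function(mask, somata, spacing, adopt_fragments_um = 6) {
  dims <- dim(mask)
  markers <- integer(prod(dims))
  usable <- integer(0)
  for (i in seq_along(somata$voxels)) {
    vox <- somata$voxels[[i]]
    inside <- vox[mask[vox]]
    if (!length(inside)) {
      warning("soma ", i, " lies outside the mask; rejected")
      next
    }
    markers[inside] <- i
    usable <- c(usable, i)
  }
  if (!length(usable)) {
    warning("no usable soma markers; returning empty label map")
    return(structure(list(labels = array(0L, dims), spacing = spacing,
                          somata = somata$somata[0, ]), class = "cell_label_map"))
  }
  d2 <- cpp_sqdist_to_true(!mask, dims, spacing)
  relief <- -sqrt(pmax(d2, 0))
  lab <- cpp_watershed(relief, markers, as.logical(mask), dims)
  if (adopt_fragments_um > 0 && any(mask & lab == 0L)) {
    # adopt detached fragments: per usable marker, distance to its basin
    dmin <- NULL; amin <- NULL
    for (u in usable) {
      sel <- lab == u
      dim(sel) <- dims
      du <- cpp_sqdist_to_true(sel, dims, spacing)
      if (is.null(dmin)) { dmin <- du; amin <- rep(u, length(du)) }
      else { upd <- du < dmin; dmin[upd] <- du[upd]; amin[upd] <- u }
    }
    orphan <- which(mask & lab == 0L)
    ok <- orphan[dmin[orphan] <= adopt_fragments_um^2]
    lab[ok] <- amin[ok]
  }
  # dense ids 1..n in soma order
  remap <- integer(max(usable)); remap[usable] <- seq_along(usable)
  pos <- lab > 0L
  lab[pos] <- remap[lab[pos]]
  dim(lab) <- dims
  structure(list(labels = lab, spacing = spacing,
                 somata = somata$somata[somata$somata$id %in% usable, , drop = FALSE]),
            class = "cell_label_map")
}

#' @export
print.cell_label_map <- function(x, ...) {
  n <- max(x$labels)
  cat(sprintf("cell_label_map: %d cell(s), %d labelled voxels\n", n, sum(x$labels > 0)))
  invisible(x)
}

#' Keep only individual, complete microglial cells
#'
#' Rejects basins that touch the stack border, contain a number of somata
#' different from one, or fall outside the volume gate. Per-cell rejection
#' reasons are recorded in the returned table.
#'
#' @param labelmap a `cell_label_map`.
#' @param somata the `soma_set` used for seeding.
#' @param min_volume,max_volume accepted-cell volume gate, um^3.
#' @return the label map with a `cells` data.frame attached (id, voxel
#'   count, volume, touches_border, n_somata, accepted, reason).
#' @export
filter_individual_cells <- function(labelmap, somata, min_volume = 200,
                                    max_volume = 20000) {
  lab <- labelmap$labels
  dims <- dim(lab)
  voxvol <- prod(labelmap$spacing)
  n <- max(lab)
  border <- array(FALSE, dims)
  border[c(1, dims[1]), , ] <- TRUE
  border[, c(1, dims[2]), ] <- TRUE
  border[, , c(1, dims[3])] <- TRUE
  rows <- list()
  for (i in seq_len(n)) {
    vox <- which(lab == i)
    vol <- length(vox) * voxvol
    tb <- any(border[vox])
    nsoma <- sum(vapply(somata$voxels, function(sv) any(lab[sv] == i), logical(1)))
    reason <- ""
    if (tb) reason <- "border"
    else if (nsoma != 1L) reason <- "multi-soma"
    else if (vol < min_volume) reason <- "too-small"
    else if (vol > max_volume) reason <- "too-large"
    rows[[i]] <- data.frame(id = i, voxel_count = length(vox), volume = vol,
                            touches_border = tb, n_somata = nsoma,
                            accepted = reason == "", reason = reason,
                            stringsAsFactors = FALSE)
  }
  labelmap$cells <- if (n) do.call(rbind, rows)
                    else data.frame(id = integer(0), voxel_count = integer(0),
                                    volume = numeric(0), touches_border = logical(0),
                                    n_somata = integer(0), accepted = logical(0),
                                    reason = character(0))
  labelmap
}

#' Full segmentation chain for one stack
#'
#' Contrast enhancement, Li global threshold, mask simplification,
#' Phansalkar soma detection, marker-controlled watershed, and the
#' individual-cell filter, with all constants drawn from the configuration.
#'
#' @param stack an [image_stack()].
#' @param config a [pipeline_config()].
#' @return list: `labels` (filtered `cell_label_map`), `somata`, `mask`,
#'   `threshold`.
#' @export
segment_stack <- function(stack, config = pipeline_config()) {
  d <- dim(stack$voxels)
  br <- min(config$clahe_block_radius_px, (min(d[2], d[3]) - 1) %/% 2)
  enh <- enhance_local_contrast(stack, br,
                                config$clahe_max_slope, config$clahe_bins)
  thr <- if (isTRUE(config$li_per_slice)) {
    sapply(seq_len(dim(enh$voxels)[1]), function(z) li_threshold(enh$voxels[z, , ],
                                                                 config$li_tol,
                                                                 config$li_max_iter))
  } else li_threshold(enh, config$li_tol, config$li_max_iter)
  mask <- if (length(thr) == 1L) enh$voxels > thr
          else sweep(enh$voxels, 1, thr, ">")
  mask <- simplify_mask(mask, config$opening_radius_px, config$closing_radius_px)
  # despeckle: drop foreground components too small to be cell material
  if (config$min_object_volume > 0) {
    cc <- cpp_label3d(as.logical(mask), d, 26L)
    sizes <- tabulate(cc[cc > 0L], nbins = max(cc, 1L))
    small <- which(sizes * prod(stack$spacing) < config$min_object_volume)
    if (length(small)) mask[cc %in% small] <- FALSE
  }
  somata <- phansalkar_soma_detect(enh, config$phansalkar_radius_px,
                                   config$phansalkar_k, config$phansalkar_p,
                                   config$phansalkar_q, config$phansalkar_r,
                                   config$soma_opening_px,
                                   config$soma_min_volume, config$soma_max_volume)
  labels <- watershed_split(mask, somata, stack$spacing,
                            adopt_fragments_um = config$fragment_adoption_um)
  labels <- filter_individual_cells(labels, somata,
                                    config$cell_min_volume, config$cell_max_volume)
  list(labels = labels, somata = somata, mask = mask, threshold = thr)
}
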